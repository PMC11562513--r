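## Toy MHC class I binding predictor.
##
## Deterministic stand-in for an ensemble of peptide-MHC binding algorithms.
## Each allele carries a fixed 9-position x 20-residue weight matrix; each
## "algorithm" applies a fixed multiplicative perturbation of that matrix, so
## the ensemble median is well defined and non-degenerate. Scores are mapped
## to a pseudo-IC50 in (0, 50000] nM via IC50 = 50000^(1 - score), which
## spans the conventional 500 nM binder threshold.

.allele_cache <- new.env(parent = emptyenv())

#' Default HLA class I allele identifiers used by the synthetic cohort
#'
#' @return character vector of allele names.
#' @export
toy_alleles <- function() {
  c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*24:02",
    "HLA-B*07:02", "HLA-B*08:01", "HLA-B*15:01", "HLA-B*44:02",
    "HLA-C*03:04", "HLA-C*04:01", "HLA-C*07:01", "HLA-C*07:02")
}

#' Default algorithm identifiers for the toy binding ensemble
#'
#' @return character vector of four algorithm names.
#' @export
toy_algorithms <- function() paste0("toyMHC-", 1:4)

## Position weight matrix for an allele: 9 positions x 20 residues in [0, 1].
## Per position one consensus residue has weight 1 and two secondary residues
## weight in [0.5, 0.9]; remaining residues are in [0, 0.3]. Alanine is fixed
## at 0.05 everywhere (a flat baseline residue, never consensus), so
## poly-alanine peptides are guaranteed weak binders for every allele.
allele_weight_matrix <- function(allele, algorithm = NULL) {
  key <- paste(allele, algorithm %||% "", sep = "\r")
  cached <- .allele_cache[[key]]
  if (!is.null(cached)) return(cached)
  W <- local_seed(string_seed("allele-pwm", allele), {
    W <- matrix(runif(9L * 20L, 0, 0.3), nrow = 9L,
                dimnames = list(NULL, AA20))
    pool <- setdiff(AA20, "A")
    for (p in 1:9) {
      picks <- sample(pool, 3L)
      W[p, picks[1L]] <- 1
      W[p, picks[2:3]] <- runif(2L, 0.5, 0.9)
    }
    W[, "A"] <- 0.05
    W
  })
  if (!is.null(algorithm)) {
    M <- local_seed(string_seed("alg-perturb", allele, algorithm),
                    matrix(runif(9L * 20L, 0.85, 1.15), nrow = 9L))
    W <- pmin(W * M, 1)
  }
  .allele_cache[[key]] <- W
  W
}

#' Consensus (strongest-binding) 9-mer motif of a toy allele
#'
#' @param allele allele identifier.
#' @return a 9-residue peptide string maximizing the allele's weight matrix.
#' @export
allele_consensus <- function(allele) {
  W <- allele_weight_matrix(allele)
  paste(AA20[apply(W, 1L, which.max)], collapse = "")
}

## Anchor-aligned mapping of peptide positions onto the 9 matrix positions:
## the four N-terminal residues map to matrix columns 1-4 (position 2 anchor),
## the four C-terminal residues to 6-9 (C-terminal anchor), and any middle
## residues all read matrix position 5.
position_map <- function(len) {
  stopifnot(len >= 8L, len <= 11L)
  c(1:4, rep(5L, len - 8L), 6:9)
}

#' Deterministic pseudo-IC50 from the toy binding predictor
#'
#' Vectorized over peptides. All peptides of length 8-11 composed of the 20
#' canonical residues are scored; the score is the mean positional weight
#' under the allele's (algorithm-perturbed) matrix, and
#' `IC50 = 50000^(1 - score)` nM.
#'
#' @param peptides character vector of 8-11-mer peptides.
#' @param allele allele identifier (any string; unknown alleles get their own
#'   deterministic weight table).
#' @param algorithm algorithm identifier (see [toy_algorithms()]).
#' @return numeric vector of IC50 values in (0, 50000] nM.
#' @export
toy_binding_oracle <- function(peptides, allele, algorithm = "toyMHC-1") {
  stopifnot(length(allele) == 1L, length(algorithm) == 1L)
  if (length(peptides) == 0L) return(numeric(0))
  lens <- nchar(peptides)
  if (any(lens < 8L | lens > 11L))
    stop_input("peptides must be 8-11 residues long")
  if (!all(is_canonical_protein(peptides)))
    stop_input("peptides must use the 20 canonical amino acid residues")
  W <- allele_weight_matrix(allele, algorithm)
  out <- numeric(length(peptides))
  for (L in unique(lens)) {
    idx <- which(lens == L)
    pm <- position_map(L)
    chars <- matrix(match(unlist(strsplit(peptides[idx], "")), AA20),
                    nrow = L)
    sc <- colSums(matrix(W[cbind(rep(pm, length(idx)), as.vector(chars))],
                         nrow = L)) / L
    out[idx] <- 50000^(1 - sc)
  }
  out
}

#' Aggregate an ensemble of binding predictions for one epitope
#'
#' Computes the across-algorithm median IC50 for the mutant peptide and, when
#' available, the matched wild-type peptide, plus the wild-type/mutant fold
#' change (> 1 means the mutant binds tighter).
#'
#' @param mt_scores numeric vector of per-algorithm mutant IC50s (>= 1 value).
#' @param wt_scores matching wild-type IC50s (same length), or `NULL` for
#'   epitopes without a wild-type partner (frameshift).
#' @return list with `median_mt_ic50`, `median_wt_ic50` (`NA` if no WT) and
#'   `fold_change` (`NA` if no WT).
#' @export
aggregate_ensemble <- function(mt_scores, wt_scores = NULL) {
  if (length(mt_scores) == 0L || !is.numeric(mt_scores))
    stop_input("at least one mutant IC50 score is required")
  if (!is.null(wt_scores) && length(wt_scores) != length(mt_scores))
    stop_input("wild-type score list must match the mutant list in length")
  mmt <- median(mt_scores)
  if (is.null(wt_scores)) {
    list(median_mt_ic50 = mmt, median_wt_ic50 = NA_real_,
         fold_change = NA_real_)
  } else {
    mwt <- median(wt_scores)
    list(median_mt_ic50 = mmt, median_wt_ic50 = mwt,
         fold_change = mwt / mmt)
  }
}

#' Score epitope pairs across the toy algorithm ensemble
#'
#' Table-level driver: for each (mutant peptide, wild-type peptide, allele)
#' row, runs every algorithm and aggregates medians and fold change.
#'
#' @param pairs data frame with columns `mt_peptide`, `wt_peptide` (`NA`
#'   allowed) and `allele`.
#' @param algorithms character vector of algorithm identifiers.
#' @param predictor prediction function with the signature of
#'   [toy_binding_oracle()]; replace to plug in external predictions.
#' @return `pairs` with columns `median_mt_ic50`, `median_wt_ic50`,
#'   `fold_change` appended.
#' @export
score_epitopes <- function(pairs, algorithms = toy_algorithms(),
                           predictor = toy_binding_oracle) {
  stopifnot(all(c("mt_peptide", "allele") %in% names(pairs)))
  n <- nrow(pairs)
  if (n == 0L) {
    pairs$median_mt_ic50 <- pairs$median_wt_ic50 <- pairs$fold_change <-
      numeric(0)
    return(pairs)
  }
  wt <- pairs$wt_peptide %||% rep(NA_character_, n)
  has_wt <- !is.na(wt)
  mt_mat <- matrix(NA_real_, n, length(algorithms))
  wt_mat <- matrix(NA_real_, n, length(algorithms))
  for (al in unique(pairs$allele)) {
    rows <- which(pairs$allele == al)
    for (j in seq_along(algorithms)) {
      mt_mat[rows, j] <- predictor(pairs$mt_peptide[rows], al, algorithms[j])
      wrows <- rows[has_wt[rows]]
      if (length(wrows))
        wt_mat[wrows, j] <- predictor(wt[wrows], al, algorithms[j])
    }
  }
  pairs$median_mt_ic50 <- apply(mt_mat, 1L, median)
  pairs$median_wt_ic50 <- ifelse(has_wt, apply(wt_mat, 1L, median), NA_real_)
  pairs$fold_change <- pairs$median_wt_ic50 / pairs$median_mt_ic50
  pairs
}
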
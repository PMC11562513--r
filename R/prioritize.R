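## Epitope prioritization: filters (median IC50, expression, anchor
## fold-change, wild-type proteome screen), clonality, driver preference,
## deterministic lexicographic ranking, and per-patient selection of 4-20
## vaccine windows with a two-step threshold relaxation.

#' Default prioritization thresholds
#'
#' @param ic50_max maximum ensemble median mutant IC50 (nM).
#' @param min_tpm minimum transcript expression; expression requires
#'   `tpm > min_tpm`.
#' @param min_alt_reads minimum mutant-allele RNA read support.
#' @param fold_min required wild-type/mutant fold change when the mutation
#'   sits on an HLA anchor position.
#' @param clonality_ratio clonal iff `vaf >= clonality_ratio * max(vaf)`
#'   within the patient.
#' @return named list of thresholds.
#' @export
default_thresholds <- function(ic50_max = 500, min_tpm = 0,
                               min_alt_reads = 1, fold_min = 1,
                               clonality_ratio = 0.5) {
  stopifnot(ic50_max > 0, min_alt_reads >= 0, fold_min > 0,
            clonality_ratio > 0, clonality_ratio <= 1)
  list(ic50_max = ic50_max, min_tpm = min_tpm,
       min_alt_reads = min_alt_reads, fold_min = fold_min,
       clonality_ratio = clonality_ratio)
}

#' Does the mutation fall on an HLA anchor position of the peptide?
#'
#' Anchor positions default to position 2 and the C-terminus, the canonical
#' class I anchor residues. Frameshift peptides (no single mutated position)
#' are never anchor overlaps by convention.
#'
#' @param mutation_pos 1-based mutated position within the peptide (`NA` for
#'   frameshift peptides).
#' @param peptide_length peptide length.
#' @param anchors anchor positions; `NA` entries stand for the C-terminus.
#' @return logical vector.
#' @export
anchor_overlap <- function(mutation_pos, peptide_length,
                           anchors = c(2L, NA)) {
  res <- logical(length(mutation_pos))
  for (i in seq_along(mutation_pos)) {
    if (is.na(mutation_pos[i])) { res[i] <- FALSE; next }
    aset <- ifelse(is.na(anchors), peptide_length[i], anchors)
    res[i] <- mutation_pos[i] %in% aset
  }
  res
}

#' Classify variant clonality from the variant allele fraction
#'
#' A variant is clonal when its VAF is at least `ratio` times the patient's
#' maximum VAF (a pragmatic surrogate for clonal architecture).
#'
#' @param vaf variant allele fraction(s).
#' @param patient_max_vaf maximum VAF observed for the patient.
#' @param ratio clonality ratio threshold.
#' @return character vector, `"clonal"` or `"subclonal"`.
#' @export
classify_clonality <- function(vaf, patient_max_vaf, ratio = 0.5) {
  stopifnot(ratio > 0, ratio <= 1)
  ifelse(vaf >= ratio * patient_max_vaf, "clonal", "subclonal")
}

#' Screen peptides for incidental matches to the wild-type proteome
#'
#' @param peptides character vector of mutant peptides.
#' @param proteome named character vector of reference proteins.
#' @return logical vector: `TRUE` if the peptide occurs as an exact
#'   substring of any reference protein.
#' @export
screen_proteome <- function(peptides, proteome) {
  if (length(peptides) == 0L) return(logical(0))
  ## "|" never occurs in protein sequence, so a concatenated scan cannot
  ## produce spurious cross-protein matches.
  blob <- paste(proteome, collapse = "|")
  uniq <- unique(peptides)
  hit <- vapply(uniq, function(p) grepl(p, blob, fixed = TRUE), logical(1))
  unname(hit[match(peptides, uniq)])
}

#' Apply the prioritization filters to annotated candidates
#'
#' A candidate passes when its ensemble median mutant IC50 is below
#' `ic50_max`, the transcript and mutant allele are expressed, the anchor
#' fold-change rule holds (fold change > `fold_min` whenever the mutation
#' lies on an anchor position; frameshift candidates are exempt), and the
#' mutant peptide does not occur in the wild-type proteome. Reason codes
#' enumerate every failed clause.
#'
#' @param candidates data frame with columns `median_mt_ic50`,
#'   `fold_change`, `anchor_overlap`, `tpm`, `rna_alt_reads`,
#'   `proteome_match`.
#' @param thresholds from [default_thresholds()].
#' @return `candidates` with logical `passes` and character `reasons`
#'   (comma-separated codes among `ic50`, `expression`, `anchor_fold`,
#'   `proteome_match`) appended.
#' @export
apply_filters <- function(candidates, thresholds = default_thresholds()) {
  th <- thresholds
  ok_ic50 <- candidates$median_mt_ic50 < th$ic50_max
  ok_expr <- candidates$tpm > th$min_tpm &
    candidates$rna_alt_reads >= th$min_alt_reads
  ok_anchor <- !candidates$anchor_overlap |
    (!is.na(candidates$fold_change) & candidates$fold_change > th$fold_min)
  ok_prot <- !candidates$proteome_match
  candidates$passes <- ok_ic50 & ok_expr & ok_anchor & ok_prot
  fail <- cbind(ic50 = !ok_ic50, expression = !ok_expr,
                anchor_fold = !ok_anchor, proteome_match = !ok_prot)
  candidates$reasons <- apply(fail, 1L, function(f)
    paste(colnames(fail)[f], collapse = ","))
  candidates
}

## Ordering permutation for candidates under the lexicographic rank key:
## passes desc, driver desc, clonal first, median MT IC50 asc, fold change
## desc (absent fold last), neoantigen id asc. Deterministic total order.
rank_order <- function(cand) {
  fold <- ifelse(is.na(cand$fold_change), -Inf, cand$fold_change)
  order(-cand$passes, -cand$driver_flag,
        ifelse(cand$clonality == "clonal", 0L, 1L),
        cand$median_mt_ic50, -fold, cand$window_id, method = "radix")
}

#' Rank candidates and select vaccine windows for one patient
#'
#' Each window is represented by its best candidate under the rank key
#' (passes, driver, clonality, median mutant IC50, fold change, id); windows
#' whose best candidate passes are selected in rank order up to
#' `max_select`. If fewer than `min_select` windows pass, thresholds are
#' relaxed stepwise (IC50 ceiling doubled, then the mutant-read requirement
#' dropped) and filtering re-run; the relaxation level used is recorded.
#'
#' @param candidates annotated candidate data frame for one patient (columns
#'   of [apply_filters()] input plus `window_id`, `driver_flag`,
#'   `clonality`).
#' @param min_select,max_select selection size bounds.
#' @param thresholds base thresholds.
#' @param relax_steps list of functions, each taking and returning a
#'   threshold list; applied cumulatively.
#' @return list with `selection` (ranked data frame of selected windows and
#'   their best candidates), `n_selected`, `relax_level` (0 = none),
#'   `status` (`"ok"` or `"empty"`), and `ranked` (all windows ranked).
#' @export
rank_and_select <- function(candidates, min_select = 4L, max_select = 20L,
                            thresholds = default_thresholds(),
                            relax_steps = list(
                              function(th) { th$ic50_max <- th$ic50_max * 2; th },
                              function(th) { th$min_alt_reads <- 0; th })) {
  stopifnot(min_select >= 1L, max_select >= min_select)
  th <- thresholds
  level <- 0L
  repeat {
    cand <- apply_filters(candidates, th)
    cand <- cand[rank_order(cand), , drop = FALSE]
    best <- cand[!duplicated(cand$window_id), , drop = FALSE]
    passing <- best[best$passes, , drop = FALSE]
    if (nrow(passing) >= min_select || level >= length(relax_steps)) break
    level <- level + 1L
    th <- relax_steps[[level]](th)
  }
  sel <- head(passing, max_select)
  sel$rank <- seq_len(nrow(sel))
  if (nrow(sel) == 0L)
    warning("no candidate windows pass filters, even after relaxation")
  list(selection = sel, n_selected = nrow(sel), relax_level = level,
       status = if (nrow(sel)) "ok" else "empty", ranked = best)
}

#' Annotate enumerated epitopes into prioritization candidates
#'
#' Joins windows (variant annotations) onto scored epitope pairs and derives
#' the per-candidate flags: anchor overlap, clonality (relative to the
#' patient's maximum VAF), and wild-type proteome match.
#'
#' @param scored scored epitope pairs from [score_epitopes()] (with
#'   `window_id`, `mutation_pos_in_peptide`, `length`).
#' @param windows window table from [build_windows()] (with `neoantigen_id`,
#'   `vaf`, `tpm`, `rna_alt_reads`, `driver_flag`).
#' @param proteome named character vector of reference proteins.
#' @param thresholds threshold list (for the clonality ratio).
#' @param anchors anchor positions, see [anchor_overlap()].
#' @return candidate data frame ready for [rank_and_select()].
#' @export
annotate_candidates <- function(scored, windows, proteome,
                                thresholds = default_thresholds(),
                                anchors = c(2L, NA)) {
  i <- match(scored$window_id, windows$neoantigen_id)
  if (anyNA(i)) stop_input("scored epitopes reference unknown windows")
  for (col in c("vaf", "tpm", "rna_alt_reads", "driver_flag"))
    scored[[col]] <- windows[[col]][i]
  scored$anchor_overlap <- anchor_overlap(scored$mutation_pos_in_peptide,
                                          scored$length, anchors)
  scored$clonality <- classify_clonality(scored$vaf, max(windows$vaf),
                                         thresholds$clonality_ratio)
  scored$proteome_match <- screen_proteome(scored$mt_peptide, proteome)
  scored
}
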
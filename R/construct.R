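## Polyepitope vaccine construct assembly: ubiquitin(G76V) fused N-terminally
## to the ordered selected windows, reverse translation to DNA with a human
## codon-usage table, junctional-epitope reporting, and the 15/16-mer
## overlapping-peptide monitoring panel.

#' Canonical human ubiquitin monomer sequence (76 residues)
#'
#' Read from the packaged reference file.
#'
#' @return the 76-residue ubiquitin protein string.
#' @export
ubiquitin_human <- function() {
  f <- system.file("extdata", "ubiquitin_human.fasta", package = "neovax")
  as.character(Biostrings::readAAStringSet(f))[[1L]]
}

#' Introduce the G76V mutation into ubiquitin
#'
#' The G76V substitution removes the C-terminal glycine required for
#' deubiquitination, making the fusion non-cleavable and routing the
#' polyepitope into proteasomal processing. The input is validated rather
#' than assumed: it must be 76 residues with glycine at position 76.
#'
#' @param wild_type_ub ubiquitin protein string (defaults to the packaged
#'   human sequence).
#' @return the mutant ubiquitin (position 76 = V).
#' @export
mutate_ubiquitin <- function(wild_type_ub = ubiquitin_human()) {
  if (nchar(wild_type_ub) != 76L)
    stop_input("ubiquitin must be 76 residues, got ", nchar(wild_type_ub))
  if (substr(wild_type_ub, 76L, 76L) != "G")
    stop_input("residue 76 must be glycine (G), got '",
               substr(wild_type_ub, 76L, 76L), "'")
  paste0(substr(wild_type_ub, 1L, 75L), "V")
}

#' Assemble the polyepitope protein with an N-terminal Ub(G76V) fusion
#'
#' Concatenates the selected windows (in the supplied order, by default the
#' selection rank order) onto the mutant ubiquitin, with no linkers unless a
#' linker string is given. Junction-spanning 8-11-mers are enumerated and
#' reported; if a predictor and alleles are supplied, junctional peptides
#' predicted to bind below `junction_ic50` are flagged. The report is
#' informational only - epitope order is never changed silently.
#'
#' @param ub_mut mutant ubiquitin from [mutate_ubiquitin()].
#' @param selection data frame with `window_id` (or `neoantigen_id`) and
#'   `mt_sequence` columns, in the desired order.
#' @param linker optional inter-epitope linker string (default none).
#' @param predictor optional binding predictor (signature of
#'   [toy_binding_oracle()]) used to score junctional peptides.
#' @param alleles alleles to score junctional peptides against.
#' @param junction_ic50 flag threshold (nM) for junctional binders.
#' @return list of class `neovax_construct`: `protein_sequence`,
#'   `ub_mut_sequence`, `epitope_order`, `segments` (per-segment start/end in
#'   the protein, 1-based), and `junction_report`.
#' @export
assemble_polyepitope <- function(ub_mut, selection, linker = "",
                                 predictor = NULL, alleles = NULL,
                                 junction_ic50 = 500) {
  ids <- selection$window_id %||% selection$neoantigen_id
  if (is.null(ids) || nrow(selection) == 0L)
    stop_input("selection must contain at least one window")
  if (anyDuplicated(ids))
    stop_input("duplicate window ids in selection: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  segs <- c(ub_mut, as.vector(rbind(rep(linker, length(ids)),
                                    selection$mt_sequence)))
  segs <- segs[nchar(segs) > 0L]
  protein <- paste(segs, collapse = "")
  ends <- cumsum(nchar(segs))
  starts <- ends - nchar(segs) + 1L
  seg_names <- c("ub_mut", if (nzchar(linker))
    as.vector(rbind(paste0("linker", seq_along(ids)), ids)) else ids)
  segments <- data.frame(segment = seg_names, start = starts, end = ends,
                         stringsAsFactors = FALSE)
  ## junctions between consecutive epitope-bearing segments (incl. ub|first)
  jpep <- list()
  for (j in seq_len(length(segs) - 1L)) {
    b <- ends[j]
    for (L in 8:11) {
      s <- seq.int(max(1L, b - L + 2L), min(b, nchar(protein) - L + 1L))
      if (!length(s) || s[1L] > b) next
      jpep[[length(jpep) + 1L]] <- data.frame(
        junction = paste(seg_names[j], seg_names[j + 1L], sep = "|"),
        start = s, length = L,
        peptide = substring(protein, s, s + L - 1L),
        stringsAsFactors = FALSE)
    }
  }
  junction_report <- if (length(jpep)) do.call(rbind, jpep) else
    data.frame(junction = character(0), start = integer(0),
               length = integer(0), peptide = character(0))
  if (!is.null(predictor) && !is.null(alleles) && nrow(junction_report)) {
    ic50 <- rep(Inf, nrow(junction_report))
    for (al in alleles)
      ic50 <- pmin(ic50, predictor(junction_report$peptide, al))
    junction_report$min_ic50 <- ic50
    junction_report$predicted_binder <- ic50 < junction_ic50
  }
  structure(list(protein_sequence = protein, ub_mut_sequence = ub_mut,
                 epitope_order = ids, segments = segments,
                 junction_report = junction_report),
            class = "neovax_construct")
}

#' Human codon usage table packaged with neovax
#'
#' Approximate human codon usage (frequency per thousand codons); only the
#' within-residue ranking matters for reverse translation.
#'
#' @return data frame with columns `codon`, `aa`, `freq`.
#' @export
codon_usage_human <- function() {
  f <- system.file("extdata", "codon_usage_human.tsv", package = "neovax")
  read.delim(f, stringsAsFactors = FALSE)
}

#' Reverse-translate a protein to DNA using most-frequent codons
#'
#' Deterministic: each residue maps to its highest-frequency codon in the
#' table (ties broken by alphabetical codon order). Optionally appends the
#' table's most frequent stop codon. Translating the emitted DNA under the
#' standard genetic code recovers the input protein exactly.
#'
#' @param protein protein string (canonical residues).
#' @param codon_table data frame with `codon`, `aa`, `freq`; stop codons
#'   have `aa = "*"`.
#' @param add_stop append a stop codon?
#' @return DNA string of length `3 * nchar(protein)` (+3 with stop).
#' @export
reverse_translate <- function(protein, codon_table = codon_usage_human(),
                              add_stop = TRUE) {
  if (!is_canonical_protein(protein))
    stop_input("protein must be a non-empty canonical amino acid string")
  ct <- codon_table[order(codon_table$aa, -codon_table$freq,
                          codon_table$codon), ]
  best <- ct[!duplicated(ct$aa), ]
  map <- setNames(best$codon, best$aa)
  res <- strsplit(protein, "")[[1L]]
  if (!all(res %in% names(map)))
    stop_input("residue(s) absent from codon table: ",
               paste(unique(setdiff(res, names(map))), collapse = ", "))
  dna <- paste(map[res], collapse = "")
  if (add_stop) {
    if (!"*" %in% names(map)) stop_input("codon table lacks stop codons")
    dna <- paste0(dna, map[["*"]])
  }
  dna
}

#' Translate DNA under the standard genetic code
#'
#' Convenience wrapper over Biostrings; trailing stop is dropped.
#'
#' @param dna DNA string (length a multiple of 3).
#' @return protein string.
#' @export
translate_dna <- function(dna) {
  p <- as.character(Biostrings::translate(Biostrings::DNAString(dna),
                                          no.init.codon = TRUE))
  sub("\\*$", "", p)
}

#' Design the overlapping-peptide monitoring panel for a window
#'
#' Greedy tiling from the N-terminus with 15-16-mer peptides overlapping by
#' 11 residues, the peptide lengths chosen so the final peptide ends exactly
#' at the window end; a 25-mer window yields exactly three peptides. For the
#' few window lengths where an exact 11-residue overlap is arithmetically
#' impossible with 15/16-mers, 15-mers are tiled and the final peptide is
#' anchored to the window end (overlap > 11); such panels are flagged.
#' Windows shorter than 15 residues give a single peptide equal to the
#' window, flagged short.
#'
#' @param window_seq window protein string (or a window list from
#'   [extract_window()]).
#' @param min_len,max_len peptide length bounds.
#' @param overlap target overlap between consecutive peptides (residues).
#' @return data frame with `peptide_index`, `start` (1-based), `length`,
#'   `sequence`, and attributes `exact_overlap` and `short`.
#' @export
design_overlapping_peptides <- function(window_seq, min_len = 15L,
                                        max_len = 16L, overlap = 11L) {
  if (is.list(window_seq)) window_seq <- window_seq$mt_sequence
  n <- nchar(window_seq)
  if (n < min_len) {
    out <- data.frame(peptide_index = 1L, start = 1L, length = n,
                      sequence = window_seq, stringsAsFactors = FALSE)
    attr(out, "exact_overlap") <- FALSE
    attr(out, "short") <- TRUE
    return(out)
  }
  if (n <= max_len) {
    k <- 1L
    lengths <- n
    starts <- 1L
    exact <- TRUE
  } else {
    step_max <- max_len - overlap
    k <- as.integer(ceiling((n - max_len) / step_max)) + 1L
    needed <- n + overlap * (k - 1L)
    if (needed >= min_len * k && needed <= max_len * k) {
      m <- needed - min_len * k  # number of peptides extended to max_len
      lengths <- c(rep(max_len, m), rep(min_len, k - m))
      starts <- cumsum(c(1L, head(lengths, -1L) - overlap))
      exact <- TRUE
    } else {
      lengths <- rep(min_len, k)
      starts <- 1L + (seq_len(k) - 1L) * (min_len - overlap)
      starts[k] <- n - min_len + 1L
      exact <- FALSE
    }
  }
  out <- data.frame(peptide_index = seq_len(k), start = starts,
                    length = lengths,
                    sequence = substring(window_seq, starts,
                                         starts + lengths - 1L),
                    stringsAsFactors = FALSE)
  attr(out, "exact_overlap") <- exact
  attr(out, "short") <- FALSE
  out
}

#' @export
print.neovax_construct <- function(x, ...) {
  cat("Polyepitope vaccine construct\n")
  cat("  protein length:", nchar(x$protein_sequence), "residues\n")
  cat("  epitopes:", length(x$epitope_order), "\n")
  cat("  junction-spanning 8-11-mers:", nrow(x$junction_report), "\n")
  invisible(x)
}
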
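## Peptide windows: somatic variant -> mutant protein -> ~25-mer window ->
## minimal 8-11-mer mutant/wild-type epitope pairs.
##
## Protein coordinates are 1-based in all I/O (variant-annotation
## convention); slicing is done with substr() internally.

#' Apply a protein-level somatic variant to a reference protein
#'
#' Missense variants substitute a single residue (the stated reference
#' residue must match the protein, guarding against annotation/reference
#' desynchronization). Frameshift/indel variants replace everything from the
#' variant position onward with the annotated novel tail, truncated at the
#' first stop (`*`).
#'
#' @param protein_sequence reference protein string.
#' @param variant list or one-row data frame with `position` (1-based),
#'   `ref` (reference residue, missense), `alt` (alternate residue for
#'   missense; novel downstream peptide for frameshift) and `type`
#'   (`"missense"` or `"frameshift"`).
#' @return the mutant protein sequence.
#' @export
apply_variant <- function(protein_sequence, variant) {
  pos <- as.integer(variant$position)
  n <- nchar(protein_sequence)
  if (is.na(pos) || pos < 1L || pos > n)
    stop_input("variant position ", pos, " outside protein of length ", n)
  if (variant$type == "missense") {
    have <- substr(protein_sequence, pos, pos)
    if (!identical(have, variant$ref))
      stop_input("reference mismatch at position ", pos, ": protein has '",
                 have, "', variant table says '", variant$ref, "'")
    paste0(substr(protein_sequence, 1L, pos - 1L), variant$alt,
           substr(protein_sequence, pos + 1L, n))
  } else {
    tail <- sub("\\*.*$", "", variant$alt)
    paste0(substr(protein_sequence, 1L, pos - 1L), tail)
  }
}

#' Extract the mutant peptide window around a variant
#'
#' For missense variants, takes up to `flank` (default 12) residues on each
#' side of the substituted residue, giving a window of at most
#' `2 * flank + 1` (25) residues, with a matched wild-type window. For
#' frameshift variants, takes up to `flank` residues upstream of the first
#' novel residue plus the novel tail, truncated to `max_window` residues
#' total; no wild-type partner exists.
#'
#' @param wt_protein reference protein.
#' @param mt_protein mutant protein from [apply_variant()].
#' @param variant the variant (as in [apply_variant()]); an optional
#'   `neoantigen_id` field names the window.
#' @param flank maximum flank length (residues).
#' @param max_window maximum frameshift window length (residues).
#' @return list with `neoantigen_id`, `mt_sequence`, `wt_sequence` (`NA` for
#'   frameshift), `mut_offset` (0-based index of the first altered residue
#'   within `mt_sequence`), `left_flank`, `right_flank`, `variant_type`.
#' @export
extract_window <- function(wt_protein, mt_protein, variant, flank = 12L,
                           max_window = 25L) {
  pos <- as.integer(variant$position)
  id <- variant$neoantigen_id %||%
    paste0(variant$protein_id %||% "prot", "_", variant$ref %||% "", pos,
           if (variant$type == "missense") variant$alt else "fs")
  if (variant$type == "missense") {
    n <- nchar(wt_protein)
    left <- min(flank, pos - 1L)
    right <- min(flank, n - pos)
    list(neoantigen_id = id,
         mt_sequence = substr(mt_protein, pos - left, pos + right),
         wt_sequence = substr(wt_protein, pos - left, pos + right),
         mut_offset = left, left_flank = left, right_flank = right,
         variant_type = "missense")
  } else {
    left <- min(flank, pos - 1L)
    start <- pos - left
    end <- min(nchar(mt_protein), start + max_window - 1L)
    list(neoantigen_id = id,
         mt_sequence = substr(mt_protein, start, end),
         wt_sequence = NA_character_,
         mut_offset = left, left_flank = left,
         right_flank = end - pos, variant_type = "frameshift")
  }
}

#' Enumerate minimal 8-11-mer mutant/wild-type epitope pairs from a window
#'
#' Every substring of each requested length that overlaps the mutated residue
#' (missense) or any novel residue (frameshift), crossed with every patient
#' HLA allele. Missense pairs carry the matched wild-type substring;
#' frameshift peptides have no wild-type partner.
#'
#' @param window a window from [extract_window()].
#' @param lengths peptide lengths to enumerate.
#' @param alleles character vector of patient HLA alleles.
#' @return data frame with one row per (peptide, allele): `window_id`,
#'   `mt_peptide`, `wt_peptide`, `allele`, `length`, `start_in_window`
#'   (0-based), `mutation_pos_in_peptide` (1-based; `NA` for frameshift).
#'   Empty (zero rows) when the window is shorter than every length.
#' @export
enumerate_minimal_epitopes <- function(window, lengths = 8:11, alleles) {
  n <- nchar(window$mt_sequence)
  m <- window$mut_offset + 1L  # 1-based position of first altered residue
  rows <- list()
  for (L in lengths) {
    if (n < L) next
    if (window$variant_type == "missense") {
      starts <- seq.int(max(1L, m - L + 1L), min(m, n - L + 1L))
    } else {
      # any substring touching the novel tail (positions m..n)
      starts <- seq.int(max(1L, m - L + 1L), n - L + 1L)
    }
    mt <- substring(window$mt_sequence, starts, starts + L - 1L)
    wt <- if (window$variant_type == "missense")
      substring(window$wt_sequence, starts, starts + L - 1L)
    else rep(NA_character_, length(starts))
    mp <- if (window$variant_type == "missense") m - starts + 1L
    else rep(NA_integer_, length(starts))
    rows[[length(rows) + 1L]] <- data.frame(
      window_id = window$neoantigen_id, mt_peptide = mt, wt_peptide = wt,
      length = L, start_in_window = starts - 1L,
      mutation_pos_in_peptide = mp, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(window_id = character(0), mt_peptide = character(0),
                      wt_peptide = character(0), length = integer(0),
                      start_in_window = integer(0),
                      mutation_pos_in_peptide = integer(0),
                      allele = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[rep(seq_len(nrow(out)), times = length(alleles)), , drop = FALSE]
  out$allele <- rep(alleles, each = nrow(out) / length(alleles))
  rownames(out) <- NULL
  out
}

#' Build peptide windows for a table of variants
#'
#' Table-level driver: applies each variant to its reference protein and
#' extracts the window. Variant rows that fail the reference-consistency
#' check raise an error.
#'
#' @param variants data frame with columns `patient_id`, `protein_id`,
#'   `position`, `ref`, `alt`, `type` (plus any annotation columns, which are
#'   carried through).
#' @param proteome named character vector of reference proteins.
#' @param flank,max_window see [extract_window()].
#' @return data frame of windows, one row per variant, with the annotation
#'   columns of `variants` appended.
#' @export
build_windows <- function(variants, proteome, flank = 12L, max_window = 25L) {
  stopifnot(nrow(variants) > 0L)
  out <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- as.list(variants[i, ])
    if (!v$protein_id %in% names(proteome))
      stop_input("unknown protein '", v$protein_id, "' in variant table")
    prot <- proteome[[v$protein_id]]
    v$neoantigen_id <- v$neoantigen_id %||%
      paste0(v$patient_id, "_", v$protein_id, "_", v$ref, v$position,
             if (v$type == "missense") v$alt else "fs")
    mt <- apply_variant(prot, v)
    w <- extract_window(prot, mt, v, flank = flank, max_window = max_window)
    out[[i]] <- data.frame(w, stringsAsFactors = FALSE)
  }
  wins <- do.call(rbind, out)
  extra <- setdiff(names(variants), c(names(wins), "alt", "ref", "position",
                                      "type"))
  cbind(wins, variants[, extra, drop = FALSE],
        variants[, c("position", "ref", "alt", "type"), drop = FALSE],
        row.names = NULL)
}
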
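## TCR CDR3-beta clonotype tables and vaccination-associated expansion
## testing (one-sided exact 2x2 test + Benjamini-Hochberg + fold floor).

#' Build a clonotype frequency table from raw counts
#'
#' @param counts data frame with columns `cdr3b` and `count` (plus any
#'   metadata columns, carried through). Zero-count rows are dropped.
#' @return the table with a `frequency` column (`count / total`).
#' @export
build_clonotype_table <- function(counts) {
  stopifnot(all(c("cdr3b", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop_input("clonotype counts must be >= 0")
  tab <- counts[counts$count > 0, , drop = FALSE]
  if (!nrow(tab)) stop_input("clonotype table is empty")
  tab$frequency <- tab$count / sum(tab$count)
  rownames(tab) <- NULL
  tab
}

#' Test clonotypes for pre- to post-vaccination expansion
#'
#' For every clonotype present in either table: pseudocounted frequency
#' fold change, a one-sided exact 2x2 test of (count, depth - count) pre vs
#' post (enrichment post), Benjamini-Hochberg adjustment across clonotypes,
#' and an expansion call requiring `q < alpha`, `fold >= min_fold` and a
#' raw frequency increase.
#'
#' @param pre_table,post_table clonotype tables from
#'   [build_clonotype_table()] for the same patient and condition.
#' @param pseudocount stand-in frequency numerator for clonotypes with a
#'   zero count at one timepoint (de novo or vanished clones); clones
#'   observed at both timepoints use the raw frequency ratio, so their fold
#'   ranking is pseudocount-invariant.
#' @param alpha significance level on the BH-adjusted p-values.
#' @param min_fold minimum frequency fold change.
#' @return data frame per clonotype: `cdr3b`, `count_pre`, `count_post`,
#'   `freq_pre`, `freq_post`, `fold_change`, `p_value`, `q_value`,
#'   `expanded`.
#' @export
test_expansion <- function(pre_table, post_table, pseudocount = 0.5,
                           alpha = 0.05, min_fold = 4) {
  if (!nrow(pre_table) || !nrow(post_table))
    stop_input("both clonotype tables must be non-empty")
  n_pre <- sum(pre_table$count)
  n_post <- sum(post_table$count)
  clones <- sort(union(pre_table$cdr3b, post_table$cdr3b))
  c_pre <- pre_table$count[match(clones, pre_table$cdr3b)]
  c_post <- post_table$count[match(clones, post_table$cdr3b)]
  c_pre[is.na(c_pre)] <- 0L
  c_post[is.na(c_post)] <- 0L
  ## pseudocount guards zero counts only (de novo or vanished clones), so
  ## the fold-change ranking of clones observed at both timepoints does not
  ## depend on the pseudocount
  f_pre <- ifelse(c_pre > 0, c_pre / n_pre,
                  pseudocount / (n_pre + pseudocount))
  f_post <- ifelse(c_post > 0, c_post / n_post,
                   pseudocount / (n_post + pseudocount))
  fold <- f_post / f_pre
  ## One-sided exact test of the 2x2 table (count, depth - count) post vs
  ## pre: conditional on the margins, the post-timepoint count is
  ## hypergeometric, so the enrichment p-value is its upper tail.
  p <- exact_enrichment_p(c_post, c_pre, n_post, n_pre)
  q <- p.adjust(p, method = "BH")
  data.frame(cdr3b = clones, count_pre = c_pre, count_post = c_post,
             freq_pre = c_pre / n_pre, freq_post = c_post / n_post,
             fold_change = fold, p_value = p, q_value = q,
             expanded = q < alpha & fold >= min_fold &
               c_post / n_post > c_pre / n_pre,
             stringsAsFactors = FALSE)
}

#' One-sided exact enrichment p-value for 2x2 count tables
#'
#' For tables `(a, n_a - a)` vs `(b, n_b - b)`, the probability under the
#' null of equal proportions of observing at least `a` successes in the
#' first row, conditional on all margins (the hypergeometric tail; equal to
#' the one-sided Fisher exact test). Vectorized over tables.
#'
#' @param a,b success counts in the two rows.
#' @param n_a,n_b row totals.
#' @return numeric vector of p-values.
#' @export
exact_enrichment_p <- function(a, b, n_a, n_b) {
  stats::phyper(a - 1, a + b, n_a + n_b - a - b, n_a, lower.tail = FALSE)
}

#' Dominant clonotype of a repertoire
#'
#' Highest-frequency clonotype, ties broken lexicographically by CDR3-beta
#' sequence.
#'
#' @param table clonotype table from [build_clonotype_table()].
#' @return list with `cdr3b` and `frequency`.
#' @export
dominant_clonotype <- function(table) {
  ord <- order(-table$frequency, table$cdr3b, method = "radix")
  list(cdr3b = table$cdr3b[ord[1L]], frequency = table$frequency[ord[1L]])
}

#' Classify the clonal structure of a vaccination response
#'
#' @param expansion output of [test_expansion()].
#' @return `"none"` (no expanded clonotype), `"monoclonal"` (exactly one)
#'   or `"oligoclonal"` (two or more).
#' @export
classify_repertoire_response <- function(expansion) {
  n <- sum(expansion$expanded)
  if (n == 0L) "none" else if (n == 1L) "monoclonal" else "oligoclonal"
}
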
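## Tiered ELISpot response calling (screening then confirmatory t-test),
## responder classification, cumulative SFC summaries, overlapping-peptide
## deconvolution, and the ICS positivity rule.

#' Background-subtracted mean spot count
#'
#' Mean of the stimulated wells minus the mean of the matched no-peptide
#' wells, floored at zero.
#'
#' @param condition_wells integer SFC counts per 10^6 cells.
#' @param no_peptide_wells matched no-peptide (background) well counts.
#' @return adjusted mean SFC (>= 0).
#' @export
subtract_background <- function(condition_wells, no_peptide_wells) {
  if (!length(condition_wells) || !length(no_peptide_wells))
    stop_input("at least one well is required in each condition")
  max(0, mean(condition_wells) - mean(no_peptide_wells))
}

#' Screening ELISpot call
#'
#' A neoantigen screens positive when the background-subtracted
#' post-vaccination mean reaches `min_sfc` spot-forming cells per 10^6 and
#' is at least `min_fold` times the (floored) pre-vaccination mean.
#'
#' @param pre_wells,post_wells stimulated well counts at each timepoint.
#' @param bg_pre,bg_post matched no-peptide well counts.
#' @param min_sfc minimum adjusted post-vaccination SFC.
#' @param min_fold minimum post/pre fold increase.
#' @return logical.
#' @export
screening_call <- function(pre_wells, post_wells, bg_pre, bg_post,
                           min_sfc = 50, min_fold = 2) {
  adj_pre <- subtract_background(pre_wells, bg_pre)
  adj_post <- subtract_background(post_wells, bg_post)
  adj_post >= min_sfc && adj_post >= min_fold * max(adj_pre, 1)
}

#' Confirmatory ELISpot call (one-sided t-test, post > pre)
#'
#' Two-sample t-test (Welch by default) on background-subtracted well
#' counts. Requires at least two replicate wells per arm; otherwise the
#' call is indeterminate.
#'
#' @param pre_wells,post_wells stimulated well counts.
#' @param bg_pre,bg_post matched no-peptide well counts.
#' @param alpha significance level.
#' @param var_equal use the pooled-variance (Student) test instead of Welch.
#' @return list with `p_value`, `confirmed`, `mean_sfc_pre`,
#'   `mean_sfc_post`, `status` (`"ok"` or `"indeterminate"`).
#' @export
confirmatory_call <- function(pre_wells, post_wells, bg_pre, bg_post,
                              alpha = 0.05, var_equal = FALSE) {
  mean_pre <- subtract_background(pre_wells, bg_pre)
  mean_post <- subtract_background(post_wells, bg_post)
  if (length(pre_wells) < 2L || length(post_wells) < 2L) {
    return(list(p_value = NA_real_, confirmed = NA,
                mean_sfc_pre = mean_pre, mean_sfc_post = mean_post,
                status = "indeterminate"))
  }
  ## wells adjusted by the background mean (unfloored: keeps the replicate
  ## variance intact; the floor applies to the reported means only)
  x_post <- post_wells - mean(bg_post)
  x_pre <- pre_wells - mean(bg_pre)
  p <- t.test(x_post, x_pre, alternative = "greater",
              var.equal = var_equal)$p.value
  list(p_value = p, confirmed = p < alpha, mean_sfc_pre = mean_pre,
       mean_sfc_post = mean_post, status = "ok")
}

#' Deconvolve a confirmed response over the overlapping-peptide panel
#'
#' Labels the response `focused` when one overlapping peptide carries at
#' least `dominance_fraction` of the summed adjusted OP signal, otherwise
#' `mixed`; and records mutant specificity: adjusted minimal mutant peptide
#' (MT-S) signal at least `min_fold` times the (floored) wild-type (WT-S)
#' signal.
#'
#' @param op_signals numeric vector of adjusted per-OP signals.
#' @param mt_s,wt_s adjusted minimal mutant / wild-type peptide signals
#'   (`NA` if not assayed).
#' @param dominance_fraction dominance threshold.
#' @param min_fold MT-S vs WT-S fold threshold.
#' @return list with `pattern` (`"focused"`/`"mixed"`), `dominant_op`,
#'   `mt_specific` (`NA` if MT-S/WT-S not assayed).
#' @export
deconvolve <- function(op_signals, mt_s = NA, wt_s = NA,
                       dominance_fraction = 0.6, min_fold = 2) {
  tot <- sum(op_signals)
  dom <- which.max(op_signals)
  pattern <- if (tot > 0 && op_signals[dom] >= dominance_fraction * tot)
    "focused" else "mixed"
  mt_specific <- if (is.na(mt_s) || is.na(wt_s)) NA
  else mt_s >= min_fold * max(wt_s, 1)
  list(pattern = pattern, dominant_op = if (tot > 0) dom else NA_integer_,
       mt_specific = mt_specific)
}

#' Call neoantigen responses from a tidy ELISpot well table
#'
#' Runs the tiered calling per patient x neoantigen: screening on the
#' pooled-OP wells, then the confirmatory one-sided t-test for screening
#' positives; a neoantigen is confirmed when it screens positive and the
#' confirmatory p-value is below `alpha`. Per-OP and minimal-peptide
#' (MT-S/WT-S) conditions, where present, are deconvolved for confirmed
#' responses. An optional Benjamini-Hochberg adjusted column is reported
#' alongside (the per-neoantigen calls themselves are not multiplicity
#' adjusted).
#'
#' @param elispot tidy data frame with columns `patient`, `neoantigen`
#'   (`NA` for no-peptide wells), `stimulus` (`"pool"`, `"OP1"`..`"OP3"`,
#'   `"MT-S"`, `"WT-S"`, `"none"`), `timepoint` (`"pre"`/`"post"`), `well`,
#'   `count`.
#' @param alpha confirmatory significance level.
#' @param min_sfc,min_fold screening thresholds.
#' @param var_equal see [confirmatory_call()].
#' @return data frame, one row per patient x neoantigen: screening flag,
#'   confirmatory p (and BH q), confirmed flag, adjusted means, and
#'   deconvolution fields.
#' @export
call_responses <- function(elispot, alpha = 0.05, min_sfc = 50,
                           min_fold = 2, var_equal = FALSE) {
  need <- c("patient", "neoantigen", "stimulus", "timepoint", "count")
  stopifnot(all(need %in% names(elispot)))
  out <- list()
  for (pat in unique(elispot$patient)) {
    ep <- elispot[elispot$patient == pat, ]
    bg_pre <- ep$count[ep$stimulus == "none" & ep$timepoint == "pre"]
    bg_post <- ep$count[ep$stimulus == "none" & ep$timepoint == "post"]
    neos <- setdiff(unique(ep$neoantigen), NA)
    for (neo in neos) {
      en <- ep[!is.na(ep$neoantigen) & ep$neoantigen == neo, ]
      pre <- en$count[en$stimulus == "pool" & en$timepoint == "pre"]
      post <- en$count[en$stimulus == "pool" & en$timepoint == "post"]
      scr <- screening_call(pre, post, bg_pre, bg_post, min_sfc, min_fold)
      cc <- confirmatory_call(pre, post, bg_pre, bg_post, alpha, var_equal)
      confirmed <- scr && isTRUE(cc$confirmed)
      ops <- paste0("OP", 1:3)
      op_sig <- vapply(ops, function(o) {
        w <- en$count[en$stimulus == o & en$timepoint == "post"]
        if (length(w)) subtract_background(w, bg_post) else NA_real_
      }, numeric(1))
      mts <- en$count[en$stimulus == "MT-S" & en$timepoint == "post"]
      wts <- en$count[en$stimulus == "WT-S" & en$timepoint == "post"]
      dec <- if (confirmed && !anyNA(op_sig))
        deconvolve(op_sig,
                   if (length(mts)) subtract_background(mts, bg_post) else NA,
                   if (length(wts)) subtract_background(wts, bg_post) else NA)
      else list(pattern = NA_character_, dominant_op = NA_integer_,
                mt_specific = NA)
      out[[length(out) + 1L]] <- data.frame(
        patient = pat, neoantigen = neo, screening_positive = scr,
        confirmatory_p = cc$p_value, confirmed = confirmed,
        mean_sfc_pre = cc$mean_sfc_pre, mean_sfc_post = cc$mean_sfc_post,
        pattern = dec$pattern, dominant_op = dec$dominant_op,
        mt_specific = dec$mt_specific, stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, out)
  calls$q_value <- p.adjust(calls$confirmatory_p, method = "BH")
  calls
}

#' Classify patients as responders
#'
#' A patient is a responder when at least one vaccinated neoantigen is
#' confirmed.
#'
#' @param calls output of [call_responses()].
#' @return data frame per patient: `responder`, `n_immunogenic`,
#'   `n_non_immunogenic`, `n_total`.
#' @export
classify_responder <- function(calls) {
  pats <- unique(calls$patient)
  do.call(rbind, lapply(pats, function(p) {
    cp <- calls[calls$patient == p, ]
    n_imm <- sum(cp$confirmed, na.rm = TRUE)
    data.frame(patient = p, responder = n_imm >= 1L, n_immunogenic = n_imm,
               n_non_immunogenic = nrow(cp) - n_imm, n_total = nrow(cp),
               stringsAsFactors = FALSE)
  }))
}

#' Cumulative spot-forming cells per patient at a timepoint
#'
#' Sum of background-subtracted pooled-OP means over all vaccinated
#' neoantigens.
#'
#' @param calls output of [call_responses()].
#' @param timepoint `"pre"` or `"post"`.
#' @return named numeric vector, one total per patient.
#' @export
cumulative_sfc <- function(calls, timepoint = c("post", "pre")) {
  timepoint <- match.arg(timepoint)
  col <- if (timepoint == "post") "mean_sfc_post" else "mean_sfc_pre"
  tapply(calls[[col]], calls$patient, sum)
}

#' ICS positivity rule
#'
#' Strict rule: at least a `min_fold` (default twofold) increase in the
#' percentage of cytokine-positive cells from pre- to post-vaccination AND
#' at least `min_percent` (default 1%) positive cells post-vaccination. The
#' relaxed variant applies the fold criterion only.
#'
#' @param percent_pre,percent_post percent positive cells in [0, 100].
#' @param min_fold fold-increase threshold.
#' @param min_percent post-vaccination percent floor (strict rule only).
#' @return data frame with logical columns `positive_strict`,
#'   `positive_relaxed` (vectorized over inputs).
#' @export
ics_call <- function(percent_pre, percent_post, min_fold = 2,
                     min_percent = 1) {
  stopifnot(all(percent_pre >= 0 & percent_pre <= 100),
            all(percent_post >= 0 & percent_post <= 100))
  relaxed <- percent_post >= min_fold * percent_pre
  strict <- relaxed & percent_post >= min_percent
  data.frame(positive_strict = strict, positive_relaxed = relaxed)
}
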
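## Cohort-level reporting: vaccine-size statistics, responder and
## immunogenicity fractions, ICS positive counts, recurrences and the
## recurrence-free survival estimate at a requested horizon; plus the
## end-to-end analysis driver for synthetic cohorts.

#' Read a trial summary table (patient, epitopes, response, recurrence)
#'
#' Reads the tab-separated per-patient summary shipped with the package
#' (`inst/extdata/trial_summary.tsv`, the published per-patient columns of
#' the TNBC DNA-vaccine trial) or any file with the same schema.
#'
#' @param path TSV with columns `patient_id`, `n_epitopes`,
#'   `immune_response` (Y/N), `recurrence` (Y/N).
#' @return data frame with logical `immune_response` and `recurrence`.
#' @export
read_trial_summary <- function(path = system.file("extdata",
                                                  "trial_summary.tsv",
                                                  package = "neovax")) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  d$immune_response <- d$immune_response %in% c("Y", "TRUE", "yes", "1")
  d$recurrence <- d$recurrence %in% c("Y", "TRUE", "yes", "1")
  d
}

#' Cohort summary report
#'
#' Pure function of its inputs: per-cohort vaccine-size statistics
#' (median/mean/min/max/total epitopes), responder count and fraction,
#' immunogenic-epitope count and fraction, strict and relaxed ICS positive
#' counts, recurrence count, and the Kaplan-Meier survival estimate (with
#' confidence interval) at a requested horizon. Components whose inputs are
#' absent are reported as `NA`; an empty cohort yields `n = 0` with all
#' statistics undefined.
#'
#' @param n_epitopes integer vector, epitopes per vaccinated patient.
#' @param responder optional logical vector (per patient).
#' @param recurrence optional logical vector (per patient).
#' @param calls optional [call_responses()] output (for immunogenic counts;
#'   used instead of `responder` when both are given and `responder` is
#'   `NULL`).
#' @param ics optional data frame with `percent_pre`, `percent_post` (ICS
#'   counts are summed over rows after per-row calls).
#' @param survival optional data frame with `time`, `event` for the
#'   vaccinated arm.
#' @param km_horizon months at which to report the survival estimate.
#' @return list of class `neovax_report`.
#' @export
cohort_report <- function(n_epitopes, responder = NULL, recurrence = NULL,
                          calls = NULL, ics = NULL, survival = NULL,
                          km_horizon = 36) {
  n <- length(n_epitopes)
  if (n == 0L) {
    return(structure(list(n_vaccinated = 0L, epitopes = list(
      median = NA_real_, mean = NA_real_, min = NA_real_, max = NA_real_,
      total = NA_real_), responders = NA, responder_fraction = NA_real_,
      immunogenic = NA, immunogenic_fraction = NA_real_,
      ics_strict_positive = NA, ics_relaxed_positive = NA,
      recurrences = NA, km = NULL, status = "undefined: empty cohort"),
      class = "neovax_report"))
  }
  if (is.null(responder) && !is.null(calls))
    responder <- classify_responder(calls)$responder
  imm <- if (!is.null(calls)) sum(calls$confirmed, na.rm = TRUE) else NA
  icsres <- if (!is.null(ics))
    ics_call(ics$percent_pre, ics$percent_post) else NULL
  km <- if (!is.null(survival)) {
    est <- km_at(km_estimate(survival), km_horizon)
    c(list(horizon = km_horizon), est)
  } else NULL
  structure(list(
    n_vaccinated = n,
    epitopes = list(median = median(n_epitopes), mean = mean(n_epitopes),
                    min = min(n_epitopes), max = max(n_epitopes),
                    total = sum(n_epitopes)),
    responders = if (!is.null(responder)) sum(responder) else NA,
    responder_fraction = if (!is.null(responder)) mean(responder)
    else NA_real_,
    immunogenic = imm,
    immunogenic_fraction = if (!is.na(imm)) imm / sum(n_epitopes)
    else NA_real_,
    ics_strict_positive = if (!is.null(icsres))
      sum(icsres$positive_strict) else NA,
    ics_relaxed_positive = if (!is.null(icsres))
      sum(icsres$positive_relaxed) else NA,
    recurrences = if (!is.null(recurrence)) sum(recurrence) else NA,
    km = km, status = "ok"), class = "neovax_report")
}

#' @export
print.neovax_report <- function(x, ...) {
  cat("Cohort report (n vaccinated =", x$n_vaccinated, ")\n")
  if (x$n_vaccinated == 0L) { cat(" ", x$status, "\n"); return(invisible(x)) }
  with(x$epitopes, cat(sprintf(
    "  epitopes per vaccine: median %g, mean %g, range %g-%g, total %g\n",
    median, mean, min, max, total)))
  if (!is.na(x$responders))
    cat(sprintf("  responders: %d/%d (%.0f%%)\n", x$responders,
                x$n_vaccinated, 100 * x$responder_fraction))
  if (!is.na(x$immunogenic))
    cat(sprintf("  immunogenic epitopes: %d (%.0f%% of vaccinated)\n",
                x$immunogenic, 100 * x$immunogenic_fraction))
  if (!is.na(x$ics_strict_positive))
    cat("  ICS positive (strict/relaxed):", x$ics_strict_positive, "/",
        x$ics_relaxed_positive, "\n")
  if (!is.na(x$recurrences)) cat("  recurrences:", x$recurrences, "\n")
  if (!is.null(x$km))
    cat(sprintf("  RFS at %g months: %.1f%% (95%% CI %.1f-%.1f%%)\n",
                x$km$horizon, 100 * x$km$surv, 100 * x$km$lower,
                100 * x$km$upper))
  invisible(x)
}

#' Analyze a simulated cohort end to end
#'
#' Runs response calling, responder classification, ICS calls, per-epitope
#' clonotype expansion testing, the two-arm log-rank comparison, and the
#' cohort report.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param alpha significance level for response and expansion calls.
#' @return list with `calls`, `responders`, `ics_calls`, `expansion` (per
#'   patient x neoantigen: expansion table and repertoire class),
#'   `km_vaccinated`, `logrank`, `report`.
#' @export
analyze_cohort <- function(cohort, alpha = 0.05) {
  calls <- call_responses(cohort$elispot, alpha = alpha)
  responders <- classify_responder(calls)
  icsc <- cbind(cohort$ics,
                ics_call(cohort$ics$percent_pre, cohort$ics$percent_post))
  exp_rows <- list()
  cl <- cohort$clonotypes
  for (k in unique(paste(cl$patient, cl$neoantigen, sep = "\r"))) {
    parts <- strsplit(k, "\r")[[1L]]
    sub <- cl[cl$patient == parts[1L] & cl$neoantigen == parts[2L], ]
    pre <- build_clonotype_table(sub[sub$timepoint == "pre", ])
    post <- build_clonotype_table(sub[sub$timepoint == "post", ])
    ex <- test_expansion(pre, post, alpha = alpha)
    exp_rows[[k]] <- data.frame(
      patient = parts[1L], neoantigen = parts[2L],
      n_expanded = sum(ex$expanded),
      repertoire_class = classify_repertoire_response(ex),
      stringsAsFactors = FALSE)
  }
  expansion <- do.call(rbind, exp_rows)
  rownames(expansion) <- NULL
  vac <- cohort$followup[cohort$followup$arm == "vaccinated", ]
  ctl <- cohort$followup[cohort$followup$arm == "control", ]
  sel <- vapply(cohort$designs, function(d) d$n_selected, integer(1))
  rep <- cohort_report(sel, responder = responders$responder,
                       recurrence = vac$event[match(responders$patient,
                                                    vac$subject)],
                       calls = calls, ics = cohort$ics, survival = vac)
  list(calls = calls, responders = responders, ics_calls = icsc,
       expansion = expansion, km_vaccinated = km_estimate(vac),
       logrank = logrank_test(vac, ctl), report = rep)
}

#' Run the full synthetic-cohort pipeline and write its outputs
#'
#' Simulates a cohort, analyzes it, and writes tidy TSV outputs plus a JSON
#' report to `outdir`. This is the function the `neovax` command-line
#' wrapper (inst/scripts/neovax.R) calls.
#'
#' @param config a [cohort_config()].
#' @param outdir output directory (created if needed).
#' @return the [analyze_cohort()] result, invisibly.
#' @export
run_cohort_analysis <- function(config = cohort_config(), outdir = ".") {
  cohort <- simulate_cohort(config)
  res <- analyze_cohort(cohort)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(outdir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(cohort$variants, "variants.tsv")
  wt(cohort$elispot, "elispot.tsv")
  wt(cohort$ics, "ics.tsv")
  wt(cohort$clonotypes, "clonotypes.tsv")
  wt(cohort$followup, "followup.tsv")
  wt(res$calls, "response_calls.tsv")
  wt(res$responders, "responders.tsv")
  wt(res$expansion, "tcr_expansion.tsv")
  writeLines(format_report_json(res), file.path(outdir, "report.json"))
  invisible(res)
}

## minimal JSON serialization of the report (flat scalars only)
format_report_json <- function(res) {
  r <- res$report
  kv <- c(n_vaccinated = r$n_vaccinated,
          epitopes_median = r$epitopes$median,
          epitopes_mean = r$epitopes$mean, epitopes_min = r$epitopes$min,
          epitopes_max = r$epitopes$max, epitopes_total = r$epitopes$total,
          responders = r$responders, immunogenic = r$immunogenic,
          recurrences = r$recurrences,
          logrank_p = res$logrank$p_value)
  paste0("{", paste(sprintf('"%s": %s', names(kv),
                            ifelse(is.na(kv), "null",
                                   format(kv, digits = 10))),
                    collapse = ", "), "}")
}
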
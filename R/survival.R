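## Recurrence-free survival: Kaplan-Meier product-limit estimation and the
## two-group log-rank test, via the survival package, with tidy outputs.
## RFS time zero is the first vaccine injection for the vaccinated arm and
## (by design of the historical comparison) 4 months after surgery for the
## control arm; arm-specific time zeros are the caller's responsibility
## when assembling the records.

#' Kaplan-Meier product-limit estimate
#'
#' Standard conventions: subjects censored at an event time remain at risk
#' for that event; S(0) = 1 and S is a right-continuous step function.
#' Confidence bands use Greenwood variance on the log-log scale.
#'
#' @param records data frame with `time` (months, > 0) and `event`
#'   (logical or 0/1).
#' @param conf_level confidence level for the band.
#' @return data frame of class `neovax_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, `lower`, `upper` (one row per observed time).
#' @export
km_estimate <- function(records, conf_level = 0.95) {
  stopifnot(nrow(records) >= 1L, all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop_input("survival times must be > 0")
  fit <- survival::survfit(
    survival::Surv(time, as.integer(event)) ~ 1, data = records,
    conf.type = "log-log", conf.int = conf_level)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv, lower = fit$lower, upper = fit$upper)
  class(out) <- c("neovax_km", "data.frame")
  out
}

#' Survival estimate (with confidence interval) at a time horizon
#'
#' @param km a [km_estimate()] result.
#' @param at horizon (months).
#' @return list with `surv`, `lower`, `upper` at the last observed time
#'   <= `at` (1 and an undefined band if no event/censoring time precedes
#'   `at`).
#' @export
km_at <- function(km, at) {
  i <- which(km$time <= at)
  if (!length(i)) return(list(surv = 1, lower = NA_real_, upper = NA_real_))
  i <- max(i)
  list(surv = km$surv[i], lower = km$lower[i], upper = km$upper[i])
}

#' Two-group log-rank test
#'
#' @param arm_a,arm_b data frames with `time` and `event` for each arm.
#' @return list with `statistic` (chi-square, 1 df), `p_value`, `observed`
#'   and `expected` event counts per arm (order: a, b).
#' @export
logrank_test <- function(arm_a, arm_b) {
  stopifnot(nrow(arm_a) >= 1L, nrow(arm_b) >= 1L)
  dat <- rbind(
    data.frame(time = arm_a$time, event = as.integer(arm_a$event),
               arm = "a", stringsAsFactors = FALSE),
    data.frame(time = arm_b$time, event = as.integer(arm_b$event),
               arm = "b", stringsAsFactors = FALSE))
  if (any(dat$time <= 0)) stop_input("survival times must be > 0")
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = dat)
  stat <- unname(sd$chisq)
  list(statistic = stat, p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}
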
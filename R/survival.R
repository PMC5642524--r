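#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (days), >= 0
#' @param events logical/0-1 event indicators (censored = 0)
#' @return data.frame (time, n_risk, n_event, n_censor, surv): the survival
#'   step function with at-risk counts, from [survival::survfit()]
#' @export
km_curve <- function(times, events) {
  if (!length(times)) abort("empty input: no follow-up records")
  stopifnot(length(times) == length(events), all(times >= 0))
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv)
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param curve output of [km_curve()]
#' @param t times at which to evaluate S(t) (right-continuous)
#' @return numeric vector of survival probabilities
#' @export
km_surv_at <- function(curve, t) {
  steps <- curve[curve$n_event > 0, , drop = FALSE]
  vapply(t, function(ti) {
    past <- steps$surv[steps$time <= ti]
    if (length(past)) past[length(past)] else 1
  }, numeric(1))
}

#' Log-rank test across groups
#'
#' @param times,events follow-up times and event indicators
#' @param group group labels (>= 2 nonempty groups)
#' @return list (statistic, df, p_value)
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) abort("log-rank needs at least two groups")
  if (any(table(group) == 0)) abort("a group has zero observations")
  # degenerate groups (no events / one case) trigger harmless NaN warnings
  sd <- suppressWarnings(
    survival::survdiff(survival::Surv(times, as.integer(events)) ~ group))
  df <- nlevels(group) - 1
  list(statistic = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit with Breslow tie handling. Zero-variance
#' covariates are reported with coefficient 0 (hazard ratio 1) and flagged
#' rather than passed to the optimizer; suspected complete separation
#' (diverging coefficient) is flagged.
#'
#' @param data data.frame containing `time`, `event` and the covariates
#' @param covariates character vector of covariate column names (numeric
#'   encoding)
#' @param max_iter Newton-Raphson iteration cap
#' @return data.frame (term, coef, hr, hr_lower, hr_upper, se, p, note)
#' @export
cox_ph <- function(data, covariates, max_iter = 100) {
  stopifnot(all(c("time", "event") %in% names(data)))
  if (sum(data$event) < 1) abort("at least one event is required")
  const <- covariates[vapply(covariates, function(v)
    stats::var(as.numeric(data[[v]])) == 0, logical(1))]
  act <- setdiff(covariates, const)
  rows <- list()
  if (length(act)) {
    f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(act, collapse = " + ")))
    fit <- survival::coxph(f, data = data, ties = "breslow",
                           control = survival::coxph.control(
                             iter.max = max_iter, eps = 1e-9))
    if (fit$iter >= max_iter)
      abort("Cox fit did not converge in ", max_iter, " iterations")
    s <- summary(fit)
    co <- s$coefficients
    separated <- abs(co[, "coef"]) > 15
    rows[[1]] <- data.frame(
      term = rownames(co), coef = co[, "coef"], hr = exp(co[, "coef"]),
      hr_lower = exp(co[, "coef"] - stats::qnorm(0.975) * co[, "se(coef)"]),
      hr_upper = exp(co[, "coef"] + stats::qnorm(0.975) * co[, "se(coef)"]),
      se = co[, "se(coef)"], p = co[, "Pr(>|z|)"],
      note = ifelse(separated, "possible complete separation", ""))
  }
  if (length(const)) {
    rows[[length(rows) + 1]] <- data.frame(
      term = const, coef = 0, hr = 1, hr_lower = NA_real_,
      hr_upper = NA_real_, se = NA_real_, p = NA_real_,
      note = "constant covariate")
  }
  out <- do.call(rbind, rows)
  out <- out[match(covariates, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive RFS and GCSS survival records from clinical follow-up
#'
#' Relapse-free survival events are loco-regional recurrence, distant
#' metastasis or death from any cause; cancer-specific survival events are
#' deaths from a GC-related cause.
#'
#' @param clinical data.frame with case_id, followup_days, relapse_event,
#'   gc_death_event
#' @return data.frame (case_id, time, rfs_event, gcss_event)
#' @export
survival_records <- function(clinical) {
  stopifnot(all(clinical$followup_days >= 0))
  data.frame(case_id = clinical$case_id, time = clinical$followup_days,
             rfs_event = as.logical(clinical$relapse_event) |
               as.logical(clinical$gc_death_event),
             gcss_event = as.logical(clinical$gc_death_event))
}
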
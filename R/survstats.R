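#' @include conditions.R
NULL

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator of the survival function from right-censored
#' times (DFS or OS in months, measured from surgery). Subjects censored at
#' t are still at risk at t (the right-continuous convention of
#' [survival::survfit()]).
#'
#' @param times non-negative follow-up times.
#' @param events logical (or 0/1) event indicators; FALSE = censored.
#' @return data.frame with columns `time`, `n_risk`, `n_event`,
#'   `survival`; the underlying `survfit` object is attached as
#'   `attr(x, "fit")`.
#' @export
#' @examples
#' kaplanMeier(c(1, 2, 3), c(TRUE, TRUE, TRUE))$survival  # 2/3, 1/3, 0
kaplanMeier <- function(times, events) {
  if (any(is.na(times)) || any(times < 0))
    tilValidationStop("times must be non-negative")
  events <- as.logical(events)
  if (anyNA(events)) tilValidationStop("events must be logical")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, survival = fit$surv)
  attr(out, "fit") <- fit
  out
}

#' Log-rank test with Mantel-Haenszel hazard ratio
#'
#' Two-group comparison of survival curves. The hazard ratio is the
#' observed/expected ratio \eqn{(O_1/E_1)/(O_2/E_2)} (group 1 = first
#' factor level, the numerator) with a log-scale 95\% confidence interval
#' from \eqn{se(\log HR) = \sqrt{1/E_1 + 1/E_2}} — appropriate for the
#' univariate curve comparisons here, where no covariates are modelled.
#'
#' @param times,events as in [kaplanMeier()].
#' @param group two-level factor (or coercible).
#' @return a `til_test` with the chi-square statistic, `hazard_ratio`,
#'   `hr_ci` (95\%), and observed/expected counts.
#' @export
logrankTest <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(group) != 2L)
    tilContractStop("group must have exactly two levels")
  events <- as.logical(events)
  if (!any(events)) tilValidationStop("no events in either group")
  if (any(is.na(times)) || any(times < 0))
    tilValidationStop("times must be non-negative")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ group)
  O <- sd_$obs; E <- sd_$exp
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  se <- sqrt(1 / E[1] + 1 / E[2])
  ci <- exp(log(hr) + c(-1, 1) * stats::qnorm(0.975) * se)
  .tilTest("Log-rank", sd_$chisq,
           stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE),
           n = as.integer(table(group)),
           hazard_ratio = unname(hr), hr_ci = unname(ci),
           observed = unname(O), expected = unname(E))
}

#' Median split into high/low groups
#'
#' Dichotomizes a continuous variable at its median; values equal to the
#' median go to the high group (high iff value >= median).
#'
#' @param values numeric vector, n >= 2.
#' @return character vector of "high"/"low" labels.
#' @export
#' @examples
#' medianSplit(c(1, 2, 3, 4))  # low low high high
medianSplit <- function(values) {
  if (length(values) < 2L || anyNA(values))
    tilValidationStop("need at least two non-missing values")
  ifelse(values >= stats::median(values), "high", "low")
}

#' Optimal survival cutpoint by maximally selected log-rank statistic
#'
#' Scans every observed value of a continuous variable as a candidate
#' cutpoint (low: value <= cutpoint, high: value > cutpoint), keeping only
#' cutpoints that leave both groups with at least `minprop * n` patients,
#' and returns the one maximizing the standardized log-rank statistic.
#' Ties are broken toward the lower cutpoint.
#'
#' The returned p-value is the plain log-rank p at the selected cutpoint,
#' used only to accompany the Kaplan-Meier display: it is *not* corrected
#' for the maximal selection and therefore overstates significance
#' (selection bias). Treat it as descriptive.
#'
#' @param values continuous variable (e.g. a post-treatment TIL density),
#'   n >= 10.
#' @param times,events survival data aligned with `values`.
#' @param minprop minimum group-size fraction in (0, 0.5); default 0.1.
#' @return list with `cutoff`, `n_low`, `n_high`, `statistic` (standardized
#'   log-rank statistic at the cutoff), `p.value`, and `labels`
#'   ("high"/"low" per patient).
#' @export
optimalCutoffSplit <- function(values, times, events, minprop = 0.1) {
  n <- length(values)
  if (n < 10L) tilValidationStop("cutpoint search needs n >= 10")
  if (length(times) != n || length(events) != n)
    tilContractStop("values, times and events must align")
  if (!is.numeric(minprop) || minprop <= 0 || minprop >= 0.5)
    tilContractStop("minprop must lie in (0, 0.5)")
  events <- as.logical(events)
  cand <- sort(unique(values))
  nlow <- vapply(cand, function(cc) sum(values <= cc), numeric(1))
  ok <- nlow >= minprop * n & (n - nlow) >= minprop * n
  cand <- cand[ok]
  if (length(cand) < 2L)
    tilValidationStop("fewer than 2 admissible cutpoints under minprop")
  stat <- vapply(cand, function(cc) {
    g <- factor(values > cc, levels = c(FALSE, TRUE))
    sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
    sqrt(sd_$chisq)
  }, numeric(1))
  best <- which.max(stat)  # which.max takes the first (lowest) maximizer
  cutoff <- cand[best]
  labels <- ifelse(values > cutoff, "high", "low")
  list(cutoff = cutoff,
       n_low = sum(labels == "low"), n_high = sum(labels == "high"),
       statistic = stat[best],
       p.value = stats::pchisq(stat[best]^2, df = 1, lower.tail = FALSE),
       labels = labels)
}
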
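#' Beta distribution from a mean and an effective event count
#'
#' The screening and treatment-pathway probabilities come with the weighted
#' number of events underlying each estimate. The beta used in the
#' probabilistic sensitivity analysis takes that event count as its first
#' shape parameter and solves the second from the mean, so the distribution
#' reproduces both the point estimate and the information content of the
#' source data.
#'
#' @param mean Point estimate, strictly inside (0, 1).
#' @param effective_events Weighted event count behind the estimate (> 0).
#' @return Named numeric vector `c(alpha, beta)` with
#'   `alpha / (alpha + beta) == mean`.
#' @export
#' @examples
#' beta_from_probability(0.5, 10)      # symmetric: (10, 10)
#' beta_from_probability(0.0909, 906)  # alpha 906, beta ~ 9061
beta_from_probability <- function(mean, effective_events) {
  stopifnot(is.numeric(mean), is.numeric(effective_events),
            length(mean) == 1L, length(effective_events) == 1L)
  if (!is.finite(mean) || mean <= 0 || mean >= 1) {
    stop("beta_from_probability(): mean must lie strictly in (0, 1); got ",
         mean, " (degenerate distribution)", call. = FALSE)
  }
  if (!is.finite(effective_events) || effective_events <= 0) {
    stop("beta_from_probability(): effective_events must be > 0", call. = FALSE)
  }
  c(alpha = effective_events,
    beta = effective_events * (1 - mean) / mean)
}

#' Beta distribution from a mean and a standard deviation
#'
#' Method-of-moments beta on \[0, 1\]: used for the QALY trajectories, whose
#' uncertainty is specified as a standard error equal to 30% of the value.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
beta_from_mean_sd <- function(mean, sd) {
  stopifnot(length(mean) == 1L, length(sd) == 1L)
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("beta_from_mean_sd(): mean must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(sd) || sd <= 0)
    stop("beta_from_mean_sd(): sd must be > 0", call. = FALSE)
  v <- sd^2
  if (v >= mean * (1 - mean)) {
    stop("beta_from_mean_sd(): variance ", v,
         " is infeasible for a beta with mean ", mean, call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Beta effective sample size implied by a printed 95% confidence interval
#'
#' Recovers an effective number of observations from a proportion and its
#' printed symmetric 95% CI by normal-approximation moment matching
#' (`se = (hi - lo) / (2 * 1.96)`, `n = mean (1 - mean) / se^2`). Used where a
#' source table prints an interval but no event count (the GP-detection
#' probabilities of sensitivity scenario 1a).
#'
#' @param mean Proportion in (0, 1).
#' @param ci_low,ci_high 95% interval bounds.
#' @return Effective sample size (total observations, not events).
#' @export
effective_n_from_ci <- function(mean, ci_low, ci_high) {
  stopifnot(ci_low < ci_high)
  se <- (ci_high - ci_low) / (2 * stats::qnorm(0.975))
  mean * (1 - mean) / se^2
}

#' Gamma distribution from a mean and standard error
#'
#' Method of moments: `shape = (mean/se)^2`, `scale = se^2/mean`. All unit
#' costs carry a standard error of 30% of the mean, so the shape is the same
#' (1/0.09 ~ 11.1) for every cost parameter.
#'
#' @param mean Mean cost (> 0).
#' @param se Standard error (> 0).
#' @return Named numeric vector `c(shape, scale)`.
#' @export
#' @examples
#' gamma_from_mean_se(759, 0.3 * 759)
#' gamma_from_mean_se(100, 100)  # CV = 1: exponential
gamma_from_mean_se <- function(mean, se) {
  stopifnot(length(mean) == 1L, length(se) == 1L)
  if (!is.finite(mean) || mean <= 0 || !is.finite(se) || se <= 0)
    stop("gamma_from_mean_se(): mean and se must be > 0", call. = FALSE)
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Probability of responding to treatment
#'
#' Response is one minus the risk of no improvement, where the risk of no
#' improvement is the treatment's relative risk applied to the absolute risk
#' of no improvement without treatment.
#'
#' @param rr Relative risk of no improvement under treatment (>= 0).
#' @param ar Absolute risk of no improvement without treatment, in \[0, 1\].
#' @return `1 - rr * ar`.
#' @export
#' @examples
#' response_probability(0.73, 0.67)  # facilitated self-help: 0.5109
#' response_probability(0.48, 0.67)  # high-intensity therapy: 0.6784
response_probability <- function(rr, ar) {
  stopifnot(length(rr) == 1L, length(ar) == 1L)
  if (!is.finite(rr) || rr < 0) stop("response_probability(): rr must be >= 0", call. = FALSE)
  if (!is.finite(ar) || ar < 0 || ar > 1)
    stop("response_probability(): ar must lie in [0, 1]", call. = FALSE)
  if (rr * ar > 1)
    stop("response_probability(): rr * ar = ", rr * ar,
         " exceeds 1; no-improvement risk must be a probability", call. = FALSE)
  1 - rr * ar
}

#' Probability a false negative is identified later within the horizon
#'
#' Linearly rescales a detection rate observed over a source window to the
#' model horizon (41% over 36 months becomes 10.25% over 9 months).
#'
#' @param rate Detection rate over the source window, in \[0, 1\].
#' @param source_months Source observation window in months (> 0).
#' @param horizon_months Model horizon in months (> 0).
#' @return `rate * horizon_months / source_months`.
#' @export
#' @examples
#' later_identification_probability(0.41, 36, 9)
later_identification_probability <- function(rate, source_months, horizon_months) {
  stopifnot(length(rate) == 1L)
  if (!is.finite(rate) || rate < 0 || rate > 1)
    stop("later_identification_probability(): rate must lie in [0, 1]", call. = FALSE)
  if (!is.finite(source_months) || source_months <= 0 ||
      !is.finite(horizon_months) || horizon_months <= 0)
    stop("later_identification_probability(): durations must be > 0", call. = FALSE)
  out <- rate * horizon_months / source_months
  if (out > 1)
    stop("later_identification_probability(): rescaled rate ", out,
         " exceeds 1", call. = FALSE)
  out
}

#' Weighted per-woman cost of the two-stage screen
#'
#' Everyone pays for the first-stage screen; only first-stage positives go on
#' to the second stage.
#'
#' @param cost_stage1 Cost of the first-stage screen (>= 0).
#' @param cost_stage2 Cost of the second-stage screen (>= 0).
#' @param p_stage1_positive Probability of a positive first-stage screen.
#' @return `cost_stage1 + p_stage1_positive * cost_stage2`.
#' @export
#' @examples
#' two_stage_screen_cost(4.53, 9.38, 0.0895)  # ~ 5.37
two_stage_screen_cost <- function(cost_stage1, cost_stage2, p_stage1_positive) {
  if (any(!is.finite(c(cost_stage1, cost_stage2))) ||
      any(cost_stage1 < 0) || any(cost_stage2 < 0))
    stop("two_stage_screen_cost(): costs must be >= 0", call. = FALSE)
  if (any(p_stage1_positive < 0 | p_stage1_positive > 1))
    stop("two_stage_screen_cost(): p_stage1_positive must lie in [0, 1]",
         call. = FALSE)
  cost_stage1 + p_stage1_positive * cost_stage2
}
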
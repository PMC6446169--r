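#' Fit a beta distribution by the method of moments
#'
#' Solves for the shape parameters of a beta distribution whose analytic mean
#' and standard deviation equal the supplied moments:
#' `shape1 = m * (m*(1-m)/s^2 - 1)`, `shape2 = (1-m) * (m*(1-m)/s^2 - 1)`.
#' Used to turn published (mean, SD/SE) pairs for probabilities, utilities and
#' adherence into sampling distributions for probabilistic sensitivity
#' analysis.
#'
#' @param mean Mean, strictly inside (0, 1).
#' @param sd Standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @param name Parameter name used in error messages.
#' @return Named numeric vector `c(shape1, shape2)`.
#' @examples
#' fit_beta_from_moments(0.39, 0.33)  # moderate-to-severe pain utility
#' @export
fit_beta_from_moments <- function(mean, sd, name = "parameter") {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop(sprintf("'%s': beta mean must lie strictly in (0, 1), got %g", name, mean))
  if (!is.finite(sd) || sd <= 0)
    stop(sprintf("'%s': beta sd must be positive, got %g", name, sd))
  v <- sd^2
  if (v >= mean * (1 - mean))
    stop(sprintf(
      "'%s': infeasible beta moments, sd^2 (%.6g) >= mean*(1-mean) (%.6g)",
      name, v, mean * (1 - mean)))
  nu <- mean * (1 - mean) / v - 1
  c(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Fit a gamma distribution by the method of moments
#'
#' `shape = (mean/sd)^2`, `scale = sd^2/mean`; the fitted distribution
#' reproduces the supplied mean and standard deviation exactly.
#'
#' @param mean Mean, strictly positive.
#' @param sd Standard deviation, strictly positive.
#' @param name Parameter name used in error messages.
#' @return Named numeric vector `c(shape, scale)`.
#' @examples
#' fit_gamma_from_moments(11.06, 3.78)  # cannabis price per gram
#' @export
fit_gamma_from_moments <- function(mean, sd, name = "parameter") {
  if (!is.finite(mean) || mean <= 0)
    stop(sprintf("'%s': gamma mean must be positive, got %g", name, mean))
  if (!is.finite(sd) || sd <= 0)
    stop(sprintf("'%s': gamma sd must be positive, got %g", name, sd))
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

# Triangular quantile function on [lo, hi] with the given mode.
qtriangular <- function(p, lo, mode, hi) {
  stopifnot(lo < hi, lo <= mode, mode <= hi, all(p >= 0), all(p <= 1))
  fc <- (mode - lo) / (hi - lo)
  ifelse(p < fc,
         lo + sqrt(p * (hi - lo) * (mode - lo)),
         hi - sqrt((1 - p) * (hi - lo) * (hi - mode)))
}

# Normal-theory SD on the log-odds scale from a symmetric-on-log 95% CI.
lognormal_sigma_from_ci <- function(ci_low, ci_high) {
  stopifnot(ci_low > 0, ci_high > ci_low)
  (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
}

# Beta shapes for patient-level heterogeneity draws. PSA iterations can move a
# mean close enough to 0/1 that the printed heterogeneity SD becomes
# moment-infeasible; the documented fallback clamps the mean into (0,1) and the
# SD to 95% of the feasibility bound.
beta_pars_clamped <- function(mean, sd, name = "parameter") {
  eps <- 1e-6
  m <- min(max(mean, eps), 1 - eps)
  s_max <- 0.95 * sqrt(m * (1 - m))
  s <- min(sd, s_max)
  fit_beta_from_moments(m, s, name)
}
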
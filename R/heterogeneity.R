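#' Recover a log-odds-ratio standard error from a printed confidence interval
#'
#' `se = (log(ci_high) - log(ci_low)) / (2 * z)`, with `z` the standard
#' normal quantile for the interval level (1.959964 at 95%). Used to rebuild
#' heterogeneity statistics from published odds ratios with confidence
#' intervals.
#'
#' @param ci_low,ci_high Confidence-interval bounds on the odds-ratio scale
#'   (`0 < ci_low < ci_high`).
#' @param level Confidence level of the interval (default 0.95).
#' @return Standard error of the log odds ratio.
#' @export
se_from_ci <- function(ci_low, ci_high, level = 0.95) {
  if (any(ci_low <= 0) || any(ci_high <= 0)) stop("bounds must be positive")
  if (any(ci_low >= ci_high)) stop("need ci_low < ci_high")
  z <- stats::qnorm((1 + level) / 2)
  (log(ci_high) - log(ci_low)) / (2 * z)
}

#' Cochran's Q test for heterogeneity of stratum estimates
#'
#' Computes the fixed-effect (inverse-variance) pooled estimate and the
#' dispersion of the stratum estimates around it:
#' `Q = sum w_i (beta_i - pooled)^2` with `w_i = 1 / se_i^2`, referred to a
#' chi-square distribution with `k - 1` degrees of freedom.
#'
#' @param betas Numeric vector of stratum estimates (log scale for odds
#'   ratios).
#' @param ses Positive standard errors, same length.
#' @return A `het_result`: list with `q`, `df`, `p_het`, `pooled`.
#' @export
cochran_q <- function(betas, ses) {
  if (length(betas) != length(ses)) stop("length mismatch")
  if (length(betas) < 2) stop("need at least two estimates")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - pooled)^2)
  df <- length(betas) - 1L
  out <- list(q = q, df = df,
              p_het = stats::pchisq(q, df, lower.tail = FALSE),
              pooled = pooled)
  class(out) <- "het_result"
  out
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4g on %d df, P_het = %.3g (pooled beta %.4g)\n",
              x$q, x$df, x$p_het, x$pooled))
  invisible(x)
}

#' Test for a male-female difference between two MR estimates
#'
#' Applies [cochran_q()] (1 df) to the two log-scale estimates. Both
#' estimates must be on the per-1-SD exposure scale and agree in trait,
#' outcome, and method; mismatches are refused.
#'
#' @param est_women,est_men `mr_estimate` objects for the same trait,
#'   outcome, and method.
#' @return A `het_result`.
#' @export
compare_sexes <- function(est_women, est_men) {
  stopifnot(inherits(est_women, "mr_estimate"), inherits(est_men, "mr_estimate"))
  for (f in c("trait", "outcome", "method")) {
    a <- est_women[[f]]; b <- est_men[[f]]
    if (!is.na(a) && !is.na(b) && a != b)
      stop("mismatched ", f, ": '", a, "' vs '", b, "'")
  }
  cochran_q(c(est_women$beta, est_men$beta), c(est_women$se, est_men$se))
}
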
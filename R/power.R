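#' Statistical power of a two-sample MR analysis with a binary outcome
#'
#' Closed-form, non-centrality-based power for the two-sided IVW z-test.
#' With `b = ln(or_detect)` the log odds ratio per exposure SD,
#' `v = case_fraction * (1 - case_fraction)` the outcome variance factor,
#' the non-centrality is `z = |b| * sqrt(n_total * r2_exposure * v)` and
#'
#' `power = pnorm(z - z_{1-alpha/2}) + pnorm(-z - z_{1-alpha/2})`.
#'
#' At `or_detect = 1` the power equals the test size `alpha`.
#'
#' @param n_total outcome-study sample size (cases + controls).
#' @param case_fraction proportion of cases, in (0,1).
#' @param r2_exposure variance in the exposure explained by the
#'   instruments, in (0,1).
#' @param or_detect odds ratio per exposure SD to detect, > 0.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in `[0, 1]`.
#' @export
#' @examples
#' power_binary(105318, 40675 / 105318, 0.039, 1.28)
power_binary <- function(n_total, case_fraction, r2_exposure, or_detect,
                         alpha = 0.05) {
  if (!is_scalar_number(n_total) || n_total <= 0) {
    stop_crossmr("n_total must be a positive number", "crossmr_domain_error")
  }
  if (!is_scalar_number(case_fraction) || case_fraction <= 0 ||
      case_fraction >= 1) {
    stop_crossmr("case_fraction must lie in (0,1)", "crossmr_domain_error")
  }
  if (!is_scalar_number(r2_exposure) || r2_exposure <= 0 ||
      r2_exposure >= 1) {
    stop_crossmr("r2_exposure must lie in (0,1)", "crossmr_domain_error")
  }
  if (!is_scalar_number(or_detect) || or_detect <= 0) {
    stop_crossmr("or_detect must be positive", "crossmr_domain_error")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_crossmr("alpha must lie in (0,1)", "crossmr_domain_error")
  }
  b <- log(or_detect)
  v <- case_fraction * (1 - case_fraction)
  z <- abs(b) * sqrt(n_total * r2_exposure * v)
  zcrit <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(z - zcrit) + stats::pnorm(-z - zcrit)
}
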
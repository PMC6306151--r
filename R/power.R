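#' Years of observation required for a Poisson pre/post rate test
#'
#' Sample-size calculation for detecting a percent reduction in a Poisson
#' event rate with a two-sided Wald test on the log rate ratio. With
#' expected counts `E_pre` and `E_post`, the log rate ratio has approximate
#' variance `1/E_pre + 1/E_post`; the smallest total observation time `T`
#' (in years, `2` half-year periods per year) satisfying
#'
#'   `|log(theta)| / sqrt(1/E_pre + 1/E_post) = z_{1-alpha/2} + z_{power}`
#'
#' with `theta = 1 - pct_reduction/100` is returned in closed form. Doubling
#' the baseline rate therefore halves the requirement, and larger effects,
#' lower power or larger alpha all reduce it.
#'
#' @param baseline_rate Pre-intervention events per half-year period (> 0).
#' @param pct_reduction Percent reduction to detect, in (0, 100).
#' @param alpha Two-sided significance level (default 0.05).
#' @param power Target power (default 0.80).
#' @param allocation Length-2 pre:post time allocation (default `c(1, 1)`,
#'   equal observation time before and after).
#' @return Total years of observation (pre + post), a positive scalar.
#' @examples
#' required_years(28.24, pct_reduction = 10)
#' required_years(74.65, pct_reduction = 20)
#' @export
required_years <- function(baseline_rate, pct_reduction, alpha = 0.05,
                           power = 0.80, allocation = c(1, 1)) {
  if (baseline_rate <= 0) {
    stop("required_years: baseline_rate must be > 0", call. = FALSE)
  }
  if (!(pct_reduction > 0 && pct_reduction < 100)) {
    stop("required_years: pct_reduction must be in (0, 100)", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1 && power > 0 && power < 1)) {
    stop("required_years: alpha and power must be in (0, 1)", call. = FALSE)
  }
  if (length(allocation) != 2L || any(allocation <= 0)) {
    stop("required_years: allocation must be two positive weights",
         call. = FALSE)
  }
  theta <- 1 - pct_reduction / 100
  w_pre <- allocation[1L] / sum(allocation)
  w_post <- 1 - w_pre
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  # periods_total solves 1/E_pre + 1/E_post = (log(theta)/z)^2 with
  # E_pre = rate * w_pre * periods, E_post = rate * theta * w_post * periods
  inv_info <- 1 / (baseline_rate * w_pre) +
    1 / (baseline_rate * theta * w_post)
  periods_total <- inv_info / (log(theta) / z)^2
  periods_total / 2
}
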
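#' Naive before/after Poisson contrasts
#'
#' Closed-form estimators for the per-period rate, the after-minus-before
#' rate difference and the after/before rate ratio, with Wald 95% confidence
#' intervals under a Poisson error assumption. These are the estimators a
#' two-group Poisson GLM (log link with a log-exposure offset for the ratio,
#' identity link for the difference) produces, written out explicitly.
#'
#' @name naive_before_after
NULL

Z95 <- function(level) stats::qnorm(1 - (1 - level) / 2)

#' Average per-period event rate with a Poisson Wald interval
#'
#' @param count Total event count (non-negative integer).
#' @param n_periods Number of periods the count accrued over (>= 1).
#' @param level Confidence level (default 0.95).
#' @return List of class `rate_estimate`: `count`, `n_periods`, `rate`,
#'   `ci_low`, `ci_high`. The interval is `rate +/- z * sqrt(count)/n_periods`
#'   with the lower bound clipped at 0.
#' @export
period_rate <- function(count, n_periods, level = 0.95) {
  if (n_periods < 1) stop("period_rate: n_periods must be >= 1", call. = FALSE)
  if (count < 0) stop("period_rate: count must be >= 0", call. = FALSE)
  z <- Z95(level)
  rate <- count / n_periods
  half <- z * sqrt(count) / n_periods
  structure(list(count = count, n_periods = n_periods, rate = rate,
                 ci_low = max(0, rate - half), ci_high = rate + half),
            class = "rate_estimate")
}

#' After/before rate ratio with a log-scale Wald interval
#'
#' @param count_after,periods_after Post-period count and number of periods.
#' @param count_before,periods_before Pre-period count and number of periods.
#' @param level Confidence level (default 0.95).
#' @return List of class `contrast_estimate` with fields `kind` (`"ratio"`),
#'   `estimate`, `ci_low`, `ci_high`, `degenerate`. The interval is
#'   `exp(log(estimate) +/- z * sqrt(1/count_after + 1/count_before))`; with a
#'   zero after-count the point estimate is 0 and the interval is flagged
#'   `degenerate` (undefined on the log scale) rather than silently clipped.
#' @export
rate_ratio <- function(count_after, periods_after,
                       count_before, periods_before, level = 0.95) {
  if (count_before <= 0) {
    stop("rate_ratio: count_before must be > 0", call. = FALSE)
  }
  est <- (count_after / periods_after) / (count_before / periods_before)
  if (count_after == 0) {
    return(structure(list(kind = "ratio", estimate = 0,
                          ci_low = NA_real_, ci_high = NA_real_,
                          degenerate = TRUE),
                     class = "contrast_estimate"))
  }
  z <- Z95(level)
  se <- sqrt(1 / count_after + 1 / count_before)
  structure(list(kind = "ratio", estimate = est,
                 ci_low = exp(log(est) - z * se),
                 ci_high = exp(log(est) + z * se),
                 degenerate = FALSE),
            class = "contrast_estimate")
}

#' After-minus-before rate difference with a Wald interval
#'
#' @inheritParams rate_ratio
#' @return List of class `contrast_estimate` with `kind = "difference"`. The
#'   interval is `estimate +/- z * sqrt(count_after/periods_after^2 +
#'   count_before/periods_before^2)`.
#' @export
rate_difference <- function(count_after, periods_after,
                            count_before, periods_before, level = 0.95) {
  if (periods_after <= 0 || periods_before <= 0) {
    stop("rate_difference: period counts must be > 0", call. = FALSE)
  }
  z <- Z95(level)
  est <- count_after / periods_after - count_before / periods_before
  se <- sqrt(count_after / periods_after^2 + count_before / periods_before^2)
  structure(list(kind = "difference", estimate = est,
                 ci_low = est - z * se, ci_high = est + z * se,
                 degenerate = FALSE),
            class = "contrast_estimate")
}

#' @export
print.contrast_estimate <- function(x, ...) {
  cat(sprintf("rate %s: %.4f (%.4f, %.4f)%s\n", x$kind, x$estimate,
              x$ci_low, x$ci_high,
              if (isTRUE(x$degenerate)) " [degenerate CI]" else ""))
  invisible(x)
}

#' Full before/after summary table for a panel
#'
#' One row per stratum and quantity, mirroring a three-panel layout:
#' counts (A), average 6-month rates with Poisson CIs (B), and the naive
#' rate difference / rate ratio contrasts with Wald CIs (C).
#'
#' @param panel A [half_year_panel()].
#' @param level Confidence level (default 0.95).
#' @return Data frame with columns `stratum`, `panel`, `quantity`, `period`,
#'   `estimate`, `ci_low`, `ci_high`, `degenerate`.
#' @export
before_after_table <- function(panel, level = 0.95) {
  stopifnot(inherits(panel, "half_year_panel"))
  rows <- list()
  for (s in c("all", "private", "public")) {
    ss <- split_pre_post(panel, s)
    nb <- length(ss$pre); na <- length(ss$post)
    cb <- sum(ss$pre); ca <- sum(ss$post)
    rb <- period_rate(cb, nb, level)
    ra <- period_rate(ca, na, level)
    dd <- rate_difference(ca, na, cb, nb, level)
    rr <- if (cb > 0) rate_ratio(ca, na, cb, nb, level) else
      structure(list(kind = "ratio", estimate = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, degenerate = TRUE),
                class = "contrast_estimate")
    rows[[s]] <- data.frame(
      stratum = s,
      panel = c("A", "A", "B", "B", "C", "C"),
      quantity = c("count", "count", "rate", "rate", "difference", "ratio"),
      period = c("before", "after", "before", "after", "contrast", "contrast"),
      estimate = c(cb, ca, rb$rate, ra$rate, dd$estimate, rr$estimate),
      ci_low = c(NA, NA, rb$ci_low, ra$ci_low, dd$ci_low, rr$ci_low),
      ci_high = c(NA, NA, rb$ci_high, ra$ci_high, dd$ci_high, rr$ci_high),
      degenerate = c(FALSE, FALSE, FALSE, FALSE, dd$degenerate,
                     rr$degenerate),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
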
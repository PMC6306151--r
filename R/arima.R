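#' Log-transform a count series
#'
#' @param counts Non-negative numeric vector.
#' @param shift Constant added before taking logs; required to be large
#'   enough that every shifted count is positive.
#' @return `log(counts + shift)`, elementwise natural log.
#' @export
log_transform <- function(counts, shift = 0) {
  if (any(counts + shift <= 0)) {
    stop("log_transform: counts + shift must be positive everywhere; ",
         "supply a positive shift for series containing zeros",
         call. = FALSE)
  }
  log(counts + shift)
}

#' Sample autocorrelation function
#'
#' Standard biased-denominator estimator:
#' `acf(k) = sum_{t} (y_t - ybar)(y_{t+k} - ybar) / sum_t (y_t - ybar)^2`,
#' with `acf(0) = 1`.
#'
#' @param series Numeric vector, longer than `max_lag`.
#' @param max_lag Largest lag to compute.
#' @return Numeric vector of length `max_lag + 1` (lags 0..max_lag). For a
#'   constant series all correlations are undefined and returned as `NaN`
#'   with attribute `degenerate = TRUE`.
#' @export
sample_acf <- function(series, max_lag) {
  n <- length(series)
  if (n <= max_lag) stop("sample_acf: series length must exceed max_lag",
                         call. = FALSE)
  x <- series - mean(series)
  denom <- sum(x^2)
  if (denom == 0) {
    out <- rep(NaN, max_lag + 1L)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  vapply(0:max_lag,
         function(k) sum(x[seq_len(n - k)] * x[seq_len(n - k) + k]) / denom,
         numeric(1))
}

#' Sample partial autocorrelation function
#'
#' Computed from [sample_acf()] by the Durbin-Levinson recursion: `pacf(k)`
#' is the last coefficient of the order-`k` Yule-Walker autoregression.
#'
#' @inheritParams sample_acf
#' @return Numeric vector of length `max_lag` (lags 1..max_lag); `NaN` with
#'   attribute `degenerate` for a constant series.
#' @export
sample_pacf <- function(series, max_lag) {
  rho <- sample_acf(series, max_lag)
  if (isTRUE(attr(rho, "degenerate"))) {
    out <- rep(NaN, max_lag)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  rho <- rho[-1L]  # lags 1..max_lag
  pacf <- numeric(max_lag)
  phi <- numeric(0)
  for (k in seq_len(max_lag)) {
    if (k == 1L) {
      a <- rho[1L]
    } else {
      num <- rho[k] - sum(phi * rho[(k - 1L):1L])
      den <- 1 - sum(phi * rho[seq_len(k - 1L)])
      a <- num / den
    }
    phi <- if (k == 1L) a else c(phi - a * rev(phi), a)
    pacf[k] <- a
  }
  pacf
}

#' ARIMA model order
#'
#' @param p AR order, `d` differencing order, `q` MA order (non-negative
#'   integers).
#' @return Object of class `arima_order`.
#' @export
arima_order <- function(p, d, q) {
  ord <- as.integer(c(p, d, q))
  if (any(ord < 0L)) stop("arima_order: orders must be non-negative",
                          call. = FALSE)
  structure(list(p = ord[1L], d = ord[2L], q = ord[3L]),
            class = "arima_order")
}

#' @export
format.arima_order <- function(x, ...) {
  sprintf("ARIMA(%d,%d,%d)", x$p, x$d, x$q)
}

#' @export
print.arima_order <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

#' Default candidate order grid
#'
#' All combinations of p in 0..2, d in 0..1, q in 0..2 except the degenerate
#' white-noise-only ARIMA(0,0,0): 17 candidates, covering every order the
#' diagnostics of short injury series usually point at (AR(1), MA(1), and
#' their differenced variants).
#'
#' @return List of [arima_order()] objects.
#' @export
default_arima_grid <- function() {
  grid <- expand.grid(p = 0:2, d = 0:1, q = 0:2)
  grid <- grid[!(grid$p == 0 & grid$d == 0 & grid$q == 0), ]
  unname(Map(arima_order, grid$p, grid$d, grid$q))
}

#' Fit an ARIMA model by exact Gaussian maximum likelihood
#'
#' Thin wrapper around [stats::arima()] (state-space/innovations likelihood,
#' `method = "ML"`). A constant (mean) term is included when `d = 0` and
#' omitted when `d = 1` (no drift), the usual Box-Jenkins default for short
#' series. Residuals are the one-step-ahead innovations; the first `d`
#' residuals are start-up artifacts and are excluded from RMSE computations.
#'
#' @param log_series Numeric series (typically log counts).
#' @param order An [arima_order()] or length-3 integer vector `c(p, d, q)`.
#' @return Object of class `arima_fit`: `order`, `ar_coefs`, `ma_coefs`,
#'   `constant` (`NA` when `d > 0`), `sigma2`, `residuals`, `loglik`,
#'   `converged`, `n`, `series`, and the underlying `stats::arima` object as
#'   `model`. On optimizer failure a non-converged stub is returned rather
#'   than an error, so grid searches can skip it.
#' @export
fit_arima <- function(log_series, order) {
  if (!inherits(order, "arima_order")) {
    order <- arima_order(order[1L], order[2L], order[3L])
  }
  n <- length(log_series)
  if (n <= order$p + order$d + order$q + 1L) {
    stop("fit_arima: series too short for ", format(order), call. = FALSE)
  }
  stub <- structure(list(order = order, ar_coefs = numeric(), ma_coefs = numeric(),
                         constant = NA_real_, sigma2 = NA_real_,
                         residuals = rep(NA_real_, n), loglik = NA_real_,
                         converged = FALSE, n = n, series = log_series,
                         model = NULL),
                    class = "arima_fit")
  fit <- tryCatch(
    suppressWarnings(
      stats::arima(log_series, order = c(order$p, order$d, order$q),
                   include.mean = (order$d == 0L), method = "ML")),
    error = function(e) NULL)
  if (is.null(fit) || (!is.null(fit$code) && fit$code != 0)) return(stub)
  cf <- stats::coef(fit)
  ar <- unname(cf[grep("^ar", names(cf))])
  ma <- unname(cf[grep("^ma", names(cf))])
  const <- if ("intercept" %in% names(cf)) unname(cf[["intercept"]]) else NA_real_
  # guard: reject fits on the stationarity/invertibility boundary
  ok <- TRUE
  if (length(ar) && any(Mod(polyroot(c(1, -ar))) <= 1 + 1e-8)) ok <- FALSE
  if (length(ma) && any(Mod(polyroot(c(1, ma))) < 1 - 1e-6)) ok <- FALSE
  if (!ok || !is.finite(fit$loglik)) return(stub)
  structure(list(order = order, ar_coefs = ar, ma_coefs = ma,
                 constant = const, sigma2 = fit$sigma2,
                 residuals = as.numeric(stats::residuals(fit)),
                 loglik = fit$loglik, converged = TRUE, n = n,
                 series = log_series, model = fit),
            class = "arima_fit")
}

#' @export
print.arima_fit <- function(x, ...) {
  cat(format(x$order),
      if (!x$converged) "[not converged]" else
        sprintf("sigma2 = %.5g, loglik = %.4f, RMSE = %.5g",
                x$sigma2, x$loglik, one_step_rmse(x)), "\n")
  if (length(x$ar_coefs)) cat("  ar:", signif(x$ar_coefs, 4), "\n")
  if (length(x$ma_coefs)) cat("  ma:", signif(x$ma_coefs, 4), "\n")
  if (!is.na(x$constant)) cat("  constant:", signif(x$constant, 4), "\n")
  invisible(x)
}

#' One-step-ahead root mean squared prediction error
#'
#' RMSE of the in-sample one-step-ahead innovations on the (log) model
#' scale, skipping the first `d` start-up residuals.
#'
#' @param fit A converged [fit_arima()] object.
#' @return Positive scalar.
#' @export
one_step_rmse <- function(fit) {
  stopifnot(inherits(fit, "arima_fit"))
  if (!fit$converged) stop("one_step_rmse: fit did not converge", call. = FALSE)
  r <- fit$residuals
  d <- fit$order$d
  if (d > 0L) r <- r[-seq_len(d)]
  sqrt(mean(r^2))
}

#' Select an ARIMA order by pre-period one-step RMSE
#'
#' Fits every candidate order to the (pre-intervention, log-transformed)
#' series and picks the converged candidate with the smallest one-step RMSE.
#' Ties within 1e-9 are broken by parsimony: smaller `p + q`, then smaller
#' `q`.
#'
#' @param pre_log_series Pre-period series on the log scale.
#' @param grid List of candidate [arima_order()]s (default
#'   [default_arima_grid()]).
#' @return Object of class `arima_selection`: `candidates` (data frame with
#'   p, d, q, rmse, converged — the analogue of a published candidate-RMSE
#'   table), `chosen` (an `arima_order`), and `fit` (the chosen
#'   `arima_fit`).
#' @export
select_order <- function(pre_log_series, grid = default_arima_grid()) {
  if (length(grid) == 0L) stop("select_order: empty candidate grid", call. = FALSE)
  fits <- lapply(grid, function(o) {
    tryCatch(fit_arima(pre_log_series, o), error = function(e) NULL)
  })
  keep <- !vapply(fits, is.null, logical(1))
  grid <- grid[keep]; fits <- fits[keep]
  if (length(fits) == 0L) stop("select_order: no candidate could be fitted",
                               call. = FALSE)
  conv <- vapply(fits, function(f) f$converged, logical(1))
  rmse <- vapply(fits, function(f) if (f$converged) one_step_rmse(f) else
    NA_real_, numeric(1))
  if (!any(conv)) stop("select_order: no candidate converged", call. = FALSE)
  cand <- data.frame(p = vapply(grid, `[[`, integer(1), "p"),
                     d = vapply(grid, `[[`, integer(1), "d"),
                     q = vapply(grid, `[[`, integer(1), "q"),
                     rmse = rmse, converged = conv)
  # minimal RMSE with parsimony tie-break within 1e-9
  best <- min(rmse[conv])
  tied <- which(conv & rmse <= best + 1e-9)
  ord <- order(cand$p[tied] + cand$q[tied], cand$q[tied], tied)
  pick <- tied[ord[1L]]
  structure(list(candidates = cand, chosen = grid[[pick]],
                 fit = fits[[pick]]),
            class = "arima_selection")
}

#' @export
print.arima_selection <- function(x, ...) {
  cat("ARIMA order selection over", nrow(x$candidates), "candidates\n")
  cat("chosen:", format(x$chosen), "with RMSE",
      signif(one_step_rmse(x$fit), 6), "\n")
  invisible(x)
}

#' Out-of-sample forecast path
#'
#' Minimum-MSE h-step-ahead predictions on the log scale, with prediction
#' standard errors from the innovation variance and the model's psi-weights
#' (parameter-estimation uncertainty is not propagated). `median_counts`
#' back-transforms the log means, i.e. the median of the implied log-normal
#' predictive distribution on the count scale.
#'
#' @param fit A converged [fit_arima()] object.
#' @param horizon Number of periods to forecast (>= 1).
#' @return Object of class `forecast_path`: `horizon`, `log_means`,
#'   `log_ses`, `median_counts`.
#' @export
forecast_path <- function(fit, horizon) {
  stopifnot(inherits(fit, "arima_fit"))
  if (!fit$converged) stop("forecast_path: fit did not converge", call. = FALSE)
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("forecast_path: horizon must be >= 1", call. = FALSE)
  pr <- stats::predict(fit$model, n.ahead = horizon)
  structure(list(horizon = horizon,
                 log_means = as.numeric(pr$pred),
                 log_ses = as.numeric(pr$se),
                 median_counts = exp(as.numeric(pr$pred))),
            class = "forecast_path")
}

#' @export
print.forecast_path <- function(x, ...) {
  cat("Forecast path, horizon", x$horizon, "\n")
  print(data.frame(h = seq_len(x$horizon), log_mean = x$log_means,
                   log_se = x$log_ses, median_count = x$median_counts))
  invisible(x)
}
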
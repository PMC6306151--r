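#' Configuration for the synthetic half-year count generator
#'
#' The generator mirrors the two assumptions the downstream analysis makes:
#' a latent process on the natural-log scale (linear trend + stationary ARMA
#' noise + optional intervention effect) and Poisson observation noise around
#' `exp(latent)`. Counts are therefore marginally over-dispersed
#' (Poisson-log-normal), which is what aggregate injury series look like.
#'
#' Defaults emulate the Odense dog-bite panel: 27 half-year periods with the
#' intervention after period 17, baseline rate 74.65 events per half-year
#' (the private-space pre-period average; use `log(28.24)` for the public
#' stratum), no secular trend, AR(1) latent noise with coefficient 0.5 and
#' innovation standard deviation 0.05 on the log scale.
#'
#' @param n_periods Number of half-year periods (>= 2).
#' @param intervention_index Number of pre-intervention periods
#'   (`0 < intervention_index < n_periods`).
#' @param baseline_log_level Natural log of the expected count per half-year
#'   at the start of the series.
#' @param trend_per_period Linear trend per period, log scale.
#' @param ar_coefs,ma_coefs ARMA coefficients of the latent noise; the AR
#'   polynomial must be stationary.
#' @param innovation_sd Standard deviation of the latent ARMA innovations
#'   (log scale, >= 0).
#' @param effect_shape `"none"`, `"step"` (constant from the first post
#'   period) or `"ramp"` (linear in log scale, reaching full strength after
#'   `ramp_periods` post periods).
#' @param effect_size_log Log-scale multiplicative effect at full strength
#'   (e.g. `log(0.8)` for a -20% step).
#' @param ramp_periods Post periods until a ramp reaches full strength.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_periods = 27L,
                         intervention_index = 17L,
                         baseline_log_level = log(74.65),
                         trend_per_period = 0,
                         ar_coefs = 0.5,
                         ma_coefs = numeric(),
                         innovation_sd = 0.05,
                         effect_shape = c("none", "step", "ramp"),
                         effect_size_log = 0,
                         ramp_periods = 4L) {
  effect_shape <- match.arg(effect_shape)
  n_periods <- as.integer(n_periods)
  intervention_index <- as.integer(intervention_index)
  if (n_periods < 2L) stop("synth_config: n_periods must be >= 2", call. = FALSE)
  if (!(intervention_index > 0L && intervention_index < n_periods)) {
    stop("synth_config: need 0 < intervention_index < n_periods", call. = FALSE)
  }
  if (innovation_sd < 0) stop("synth_config: innovation_sd must be >= 0", call. = FALSE)
  if (length(ar_coefs) && any(Mod(polyroot(c(1, -ar_coefs))) <= 1)) {
    stop("synth_config: AR coefficients are not stationary ",
         "(roots must lie outside the unit circle)", call. = FALSE)
  }
  if (ramp_periods < 1L) stop("synth_config: ramp_periods must be >= 1", call. = FALSE)
  structure(list(n_periods = n_periods,
                 intervention_index = intervention_index,
                 baseline_log_level = baseline_log_level,
                 trend_per_period = trend_per_period,
                 ar_coefs = ar_coefs, ma_coefs = ma_coefs,
                 innovation_sd = innovation_sd,
                 effect_shape = effect_shape,
                 effect_size_log = effect_size_log,
                 ramp_periods = as.integer(ramp_periods)),
            class = "synth_config")
}

# intervention effect profile on the log scale, one value per period
effect_profile <- function(config) {
  i <- seq_len(config$n_periods)
  post <- pmax(0L, i - config$intervention_index)  # 1,2,... in the post period
  switch(config$effect_shape,
         none = rep(0, config$n_periods),
         step = config$effect_size_log * (post > 0),
         ramp = config$effect_size_log * pmin(1, post / config$ramp_periods))
}

#' Simulate the latent log-mean series
#'
#' `latent[i] = baseline + trend * (i - 1) + ARMA noise + effect(i)`, with the
#' ARMA noise started from (approximately) its stationary distribution via a
#' 100-period burn-in. Uses the current R random number stream; call
#' `set.seed()` for reproducibility.
#'
#' @param config A [synth_config()].
#' @return Numeric vector of log means, length `n_periods`.
#' @export
simulate_latent <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_periods
  if (config$innovation_sd == 0) {
    noise <- rep(0, n)
  } else if (length(config$ar_coefs) == 0 && length(config$ma_coefs) == 0) {
    noise <- stats::rnorm(n, sd = config$innovation_sd)
  } else {
    model <- list()
    if (length(config$ar_coefs)) model$ar <- config$ar_coefs
    if (length(config$ma_coefs)) model$ma <- config$ma_coefs
    noise <- as.numeric(stats::arima.sim(
      model, n = n, sd = config$innovation_sd,
      n.start = 100L + length(config$ar_coefs) + length(config$ma_coefs)))
  }
  config$baseline_log_level +
    config$trend_per_period * (seq_len(n) - 1L) +
    noise +
    effect_profile(config)
}

#' Simulate Poisson counts around a latent log-mean series
#'
#' @param latent_log_means Numeric vector of log means (finite; `-Inf` is
#'   tolerated and yields a structural zero).
#' @return Integer vector, `counts[i] ~ Poisson(exp(latent[i]))`.
#' @export
simulate_counts <- function(latent_log_means) {
  if (any(is.na(latent_log_means)) || any(latent_log_means == Inf)) {
    stop("simulate_counts: latent log means must be finite", call. = FALSE)
  }
  lambda <- exp(latent_log_means)
  if (any(lambda > 1e9)) {
    stop("simulate_counts: rate exceeds 1e9; refusing (overflow guard)",
         call. = FALSE)
  }
  stats::rpois(length(lambda), lambda)
}

#' Simulate a stratified half-year panel
#'
#' Generates private and public strata from their own configurations (which
#' must agree on `n_periods` and `intervention_index`) and assembles a
#' [half_year_panel()] whose all-location counts are the sum of the strata.
#' Each stratum uses an independent RNG sub-stream derived from `seed`, so a
#' fixed seed reproduces the panel exactly.
#'
#' @param cfg_private,cfg_public [synth_config()] objects, one per stratum.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param start_year First calendar year of the period grid (labels only).
#' @return A [half_year_panel()] with attribute `latent` (list of the two
#'   latent log-mean series) and `configs`.
#' @export
simulate_panel <- function(cfg_private = synth_config(),
                           cfg_public = synth_config(
                             baseline_log_level = log(28.24)),
                           seed = NULL, start_year = 2002L) {
  stopifnot(inherits(cfg_private, "synth_config"),
            inherits(cfg_public, "synth_config"))
  if (cfg_private$n_periods != cfg_public$n_periods ||
      cfg_private$intervention_index != cfg_public$intervention_index) {
    stop("simulate_panel: strata must share n_periods and intervention_index",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  subseeds <- sample.int(.Machine$integer.max, 2L)

  set.seed(subseeds[1L])
  latent_priv <- simulate_latent(cfg_private)
  counts_priv <- simulate_counts(latent_priv)
  set.seed(subseeds[2L])
  latent_pub <- simulate_latent(cfg_public)
  counts_pub <- simulate_counts(latent_pub)

  n <- cfg_private$n_periods
  years <- start_year + (seq_len(n) - 1L) %/% 2L
  halves <- ifelse((seq_len(n) - 1L) %% 2L == 0L, "H1", "H2")
  panel <- half_year_panel(data.frame(year = years, half = halves),
                           counts_priv, counts_pub,
                           intervention_index = cfg_private$intervention_index)
  attr(panel, "latent") <- list(private = latent_priv, public = latent_pub)
  attr(panel, "configs") <- list(private = cfg_private, public = cfg_public)
  panel
}
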
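#' Monte Carlo effect-estimation settings
#'
#' @param iterations Number of Monte Carlo iterations (default 10000, enough
#'   for stable coefficients; the Monte Carlo standard error shrinks as
#'   `1/sqrt(iterations)`).
#' @param ui_level Central uncertainty-interval level in (0, 1)
#'   (default 0.95, i.e. the 2.5 and 97.5 percentiles).
#' @param periods_per_year Periods per year used for annualization
#'   (default 2 for half-year data).
#' @return Object of class `mc_config`.
#' @export
mc_config <- function(iterations = 10000L, ui_level = 0.95,
                      periods_per_year = 2L) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("mc_config: iterations must be >= 1", call. = FALSE)
  if (!(ui_level > 0 && ui_level < 1)) {
    stop("mc_config: ui_level must be in (0, 1)", call. = FALSE)
  }
  if (periods_per_year < 1L) {
    stop("mc_config: periods_per_year must be >= 1", call. = FALSE)
  }
  structure(list(iterations = iterations, ui_level = ui_level,
                 periods_per_year = as.integer(periods_per_year)),
            class = "mc_config")
}

#' Draw counterfactual post-period counts
#'
#' Each draw is log-normal around the forecast:
#' `draw[i, h] = exp(rnorm(log_means[h], log_ses[h]))`, independent across
#' iterations and horizons. A zero (or negative) standard error degenerates
#' to a point mass at `exp(log_means[h])`.
#'
#' @param path A [forecast_path()].
#' @param cfg An [mc_config()].
#' @return `iterations x horizon` numeric matrix on the count scale.
#' @export
draw_counterfactuals <- function(path, cfg = mc_config()) {
  stopifnot(inherits(path, "forecast_path"), inherits(cfg, "mc_config"))
  h <- path$horizon
  ses <- pmax(path$log_ses, 0)
  m <- matrix(stats::rnorm(cfg$iterations * h,
                           mean = rep(path$log_means, each = cfg$iterations),
                           sd = rep(ses, each = cfg$iterations)),
              nrow = cfg$iterations, ncol = h)
  exp(m)
}

#' Draw Poisson replicates of the observed post-period counts
#'
#' `draw[i, h] ~ Poisson(observed[h])`, representing sampling noise around
#' the realized counts.
#'
#' @param observed_counts Non-negative integer vector of observed post
#'   counts.
#' @param cfg An [mc_config()].
#' @return `iterations x horizon` numeric matrix.
#' @export
draw_observed <- function(observed_counts, cfg = mc_config()) {
  stopifnot(inherits(cfg, "mc_config"))
  if (any(observed_counts < 0) || any(observed_counts != round(observed_counts))) {
    stop("draw_observed: observed counts must be non-negative integers",
         call. = FALSE)
  }
  h <- length(observed_counts)
  matrix(stats::rpois(cfg$iterations * h,
                      lambda = rep(observed_counts, each = cfg$iterations)),
         nrow = cfg$iterations, ncol = h)
}

#' Summarize Monte Carlo intervention effects
#'
#' Per iteration `i` and post period `h`, the difference is
#' `D[i,h] = obs[i,h] - cf[i,h]` (negative = events prevented) and the
#' percent change `P[i,h] = 100 * D[i,h] / cf[i,h]`. The average annualized
#' difference is `periods_per_year * mean_h D[i,h]` and the average percent
#' change `mean_h P[i,h]`. Points are Monte Carlo means; uncertainty
#' intervals are central (equal-tailed) percentile intervals; a quantity is
#' flagged significant when its interval excludes 0. Iterations in which any
#' counterfactual draw is exactly 0 are excluded from the percent summaries
#' (their number is reported).
#'
#' @param cf_draws,obs_draws Matrices from [draw_counterfactuals()] and
#'   [draw_observed()], same shape.
#' @param cfg An [mc_config()].
#' @return Object of class `effect_summary`: `per_period` (data frame with
#'   point/UI for difference and percent per post period, plus significance
#'   flags), `avg_annualized_diff` and `avg_pct_change` (named vectors
#'   `point`, `ui_low`, `ui_high`), overall `significant` flags,
#'   `n_excluded_pct`, and the `mc_config` used.
#' @export
effect_summary <- function(cf_draws, obs_draws, cfg = mc_config()) {
  if (!all(dim(cf_draws) == dim(obs_draws))) {
    stop("effect_summary: draw matrices must have the same shape",
         call. = FALSE)
  }
  probs <- c((1 - cfg$ui_level) / 2, 1 - (1 - cfg$ui_level) / 2)
  D <- obs_draws - cf_draws

  ok <- rowSums(cf_draws == 0) == 0L
  n_excluded <- sum(!ok)
  if (n_excluded > 0L) {
    warning("effect_summary: excluded ", n_excluded,
            " iteration(s) with a zero counterfactual draw from the ",
            "percent summaries", call. = FALSE)
  }
  P <- 100 * D[ok, , drop = FALSE] / cf_draws[ok, , drop = FALSE]

  summ <- function(x) {
    qs <- unname(stats::quantile(x, probs, names = FALSE, type = 7))
    c(point = mean(x), ui_low = qs[1L], ui_high = qs[2L])
  }
  pp_diff <- t(apply(D, 2L, summ))
  pp_pct <- t(apply(P, 2L, summ))
  per_period <- data.frame(
    period = seq_len(ncol(D)),
    diff = pp_diff[, "point"], diff_low = pp_diff[, "ui_low"],
    diff_high = pp_diff[, "ui_high"],
    pct = pp_pct[, "point"], pct_low = pp_pct[, "ui_low"],
    pct_high = pp_pct[, "ui_high"])
  per_period$significant <- per_period$diff_low > 0 | per_period$diff_high < 0

  A <- cfg$periods_per_year * rowMeans(D)
  G <- rowMeans(P)
  avg_diff <- summ(A)
  avg_pct <- summ(G)
  structure(list(per_period = per_period,
                 avg_annualized_diff = avg_diff,
                 avg_pct_change = avg_pct,
                 significant = c(
                   diff = unname(avg_diff["ui_low"] > 0 | avg_diff["ui_high"] < 0),
                   pct = unname(avg_pct["ui_low"] > 0 | avg_pct["ui_high"] < 0)),
                 n_excluded_pct = n_excluded,
                 config = cfg),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat("Monte Carlo intervention effect (", x$config$iterations,
      " iterations)\n", sep = "")
  cat(sprintf("  avg annualized difference: %.2f (%.0f%% UI: %.2f, %.2f)%s\n",
              x$avg_annualized_diff["point"], 100 * x$config$ui_level,
              x$avg_annualized_diff["ui_low"], x$avg_annualized_diff["ui_high"],
              if (x$significant["diff"]) " *" else ""))
  cat(sprintf("  avg percent change:        %.2f%% (%.0f%% UI: %.2f, %.2f)%s\n",
              x$avg_pct_change["point"], 100 * x$config$ui_level,
              x$avg_pct_change["ui_low"], x$avg_pct_change["ui_high"],
              if (x$significant["pct"]) " *" else ""))
  if (x$n_excluded_pct > 0) {
    cat("  (", x$n_excluded_pct, "iterations excluded from percent summaries )\n")
  }
  invisible(x)
}

#' Aggregate per-period Monte Carlo effects into yearly effects
#'
#' Sums consecutive pairs (or `periods_per_year`-tuples) of per-period
#' differences within each iteration before summarizing, giving
#' year-by-year counterfactual effect estimates. A trailing incomplete year
#' is kept and labelled with the number of periods it covers.
#'
#' @inheritParams effect_summary
#' @return Data frame with one row per (possibly partial) post year:
#'   `year_index`, `n_periods`, `diff`, `diff_low`, `diff_high`,
#'   `significant`.
#' @export
yearly_effects <- function(cf_draws, obs_draws, cfg = mc_config()) {
  if (!all(dim(cf_draws) == dim(obs_draws))) {
    stop("yearly_effects: draw matrices must have the same shape",
         call. = FALSE)
  }
  D <- obs_draws - cf_draws
  h <- ncol(D)
  grp <- (seq_len(h) - 1L) %/% cfg$periods_per_year + 1L
  probs <- c((1 - cfg$ui_level) / 2, 1 - (1 - cfg$ui_level) / 2)
  out <- lapply(unique(grp), function(g) {
    block <- rowSums(D[, grp == g, drop = FALSE])
    qs <- unname(stats::quantile(block, probs, names = FALSE))
    data.frame(year_index = g, n_periods = sum(grp == g),
               diff = mean(block), diff_low = qs[1L], diff_high = qs[2L],
               significant = qs[1L] > 0 | qs[2L] < 0)
  })
  do.call(rbind, out)
}

#' End-to-end effect estimate for one stratum of a panel
#'
#' Convenience wrapper chaining [split_pre_post()], [log_transform()],
#' [select_order()], [forecast_path()] and the Monte Carlo summaries.
#'
#' @param panel A [half_year_panel()].
#' @param stratum `"all"`, `"private"` or `"public"`.
#' @param grid Candidate orders for [select_order()].
#' @param cfg An [mc_config()].
#' @param seed Optional integer seed for the Monte Carlo draws.
#' @param shift Passed to [log_transform()] (use a positive value if the
#'   pre-period contains zero counts).
#' @return List of class `stratum_effect`: `stratum`, `selection`, `path`,
#'   `effects` (an [effect_summary()]), `observed_post`.
#' @export
estimate_effect <- function(panel, stratum = c("all", "private", "public"),
                            grid = default_arima_grid(), cfg = mc_config(),
                            seed = NULL, shift = 0) {
  stratum <- match.arg(stratum)
  ss <- split_pre_post(panel, stratum)
  sel <- select_order(log_transform(ss$pre, shift), grid)
  path <- forecast_path(sel$fit, horizon = length(ss$post))
  if (!is.null(seed)) set.seed(as.integer(seed))
  cf <- draw_counterfactuals(path, cfg)
  obs <- draw_observed(ss$post, cfg)
  structure(list(stratum = stratum, selection = sel, path = path,
                 effects = effect_summary(cf, obs, cfg),
                 observed_post = ss$post),
            class = "stratum_effect")
}

#' @export
print.stratum_effect <- function(x, ...) {
  cat("Stratum:", x$stratum, "| chosen model:", format(x$selection$chosen),
      "\n")
  print(x$effects)
  invisible(x)
}
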
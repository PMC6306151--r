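#' Configuration for a full pipeline run
#'
#' @param panel A [half_year_panel()], or `NULL` if `events` /
#'   `panel_csv` is given.
#' @param events Optional [injury_events()] table to bin with `window`.
#' @param panel_csv Optional path to a pre-binned panel CSV.
#' @param window A [study_window()] (required when binning events).
#' @param strata Character vector of strata to analyze.
#' @param grid Candidate ARIMA orders.
#' @param mc An [mc_config()].
#' @param seed Integer seed governing all Monte Carlo draws.
#' @param out_dir Output directory (created if missing).
#' @param shift Log-transform shift for series containing zeros.
#' @return Object of class `run_config`.
#' @export
run_config <- function(panel = NULL, events = NULL, panel_csv = NULL,
                       window = odense_window(),
                       strata = c("private", "public"),
                       grid = default_arima_grid(),
                       mc = mc_config(), seed = 1L,
                       out_dir = tempfile("bitecast_run_"), shift = 0) {
  bad <- setdiff(strata, c("all", "private", "public"))
  if (length(bad)) {
    stop("run_config: unknown stratum '", bad[1L], "'", call. = FALSE)
  }
  if (length(strata) == 0L) stop("run_config: no strata requested", call. = FALSE)
  if (is.null(panel)) {
    if (!is.null(events)) {
      panel <- bin_events(events, window)
    } else if (!is.null(panel_csv)) {
      if (!file.exists(panel_csv)) {
        stop("run_config: panel_csv path does not exist: ", panel_csv,
             call. = FALSE)
      }
      panel <- read_panel_csv(panel_csv)
    } else {
      stop("run_config: supply a panel, events, or panel_csv", call. = FALSE)
    }
  }
  structure(list(panel = panel, strata = strata, grid = grid, mc = mc,
                 seed = as.integer(seed), out_dir = out_dir, shift = shift),
            class = "run_config")
}

#' Run the full intervention analysis and write all artifacts
#'
#' Sequences the pipeline end to end: before/after table, per-stratum ARIMA
#' selection with candidate RMSE table, counterfactual forecast, Monte Carlo
#' effect summaries, and plots. Every numeric artifact is reproducible under
#' the configured seed (stratum draws use sub-seeds derived from it).
#'
#' Files written to `cfg$out_dir`: `before_after_table.csv`,
#' `rmse_<stratum>.csv`, `fit_<stratum>.json`, `effects_<stratum>.json`,
#' `fit_effects_<stratum>.png`, and `run_log.json` recording chosen orders,
#' seeds and exclusions.
#'
#' @param cfg A [run_config()].
#' @return List of class `run_report`: `table`, per-stratum `results`
#'   (each a `stratum_effect`), `files`, `log`.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  tab <- wrap("naive", before_after_table(cfg$panel))
  f <- file.path(cfg$out_dir, "before_after_table.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  files <- c(files, f)

  set.seed(cfg$seed)
  subseeds <- sample.int(.Machine$integer.max, length(cfg$strata))
  results <- list()
  log <- list(seed = cfg$seed, strata = list())
  for (i in seq_along(cfg$strata)) {
    s <- cfg$strata[i]
    res <- wrap(paste0("effect[", s, "]"),
                estimate_effect(cfg$panel, s, grid = cfg$grid, cfg = cfg$mc,
                                seed = subseeds[i], shift = cfg$shift))
    results[[s]] <- res

    f <- file.path(cfg$out_dir, paste0("rmse_", s, ".csv"))
    utils::write.csv(res$selection$candidates, f, row.names = FALSE)
    files <- c(files, f)

    fit <- res$selection$fit
    f <- file.path(cfg$out_dir, paste0("fit_", s, ".json"))
    jsonlite::write_json(list(
      order = c(fit$order$p, fit$order$d, fit$order$q),
      ar = fit$ar_coefs, ma = fit$ma_coefs,
      constant = if (is.na(fit$constant)) NULL else fit$constant,
      sigma2 = fit$sigma2, loglik = fit$loglik,
      rmse = one_step_rmse(fit)), f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)

    f <- file.path(cfg$out_dir, paste0("effects_", s, ".json"))
    es <- res$effects
    jsonlite::write_json(list(
      per_period = es$per_period,
      avg_annualized_diff = as.list(es$avg_annualized_diff),
      avg_pct_change = as.list(es$avg_pct_change),
      significant = as.list(es$significant),
      iterations = es$config$iterations,
      n_excluded_pct = es$n_excluded_pct), f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)

    f <- file.path(cfg$out_dir, paste0("fit_effects_", s, ".png"))
    wrap(paste0("plot[", s, "]"),
         plot_fit_and_effects(cfg$panel, s, res$path, res$effects, f))
    files <- c(files, f)

    log$strata[[s]] <- list(
      chosen_order = format(res$selection$chosen), seed = subseeds[i],
      significant = as.list(es$significant),
      n_excluded_pct = es$n_excluded_pct)
  }

  f <- file.path(cfg$out_dir, "run_log.json")
  jsonlite::write_json(log, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  structure(list(table = tab, results = results, files = files, log = log),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run over strata:", paste(names(x$results), collapse = ", "),
      "\n")
  for (s in names(x$results)) {
    r <- x$results[[s]]
    sig <- any(unlist(r$effects$significant))
    cat(sprintf("  %-8s %s  avg %% change %.2f  -> %s\n", s,
                format(r$selection$chosen),
                r$effects$avg_pct_change["point"],
                if (sig) "significant effect" else "no significant effect"))
  }
  cat("Artifacts:", length(x$files), "files\n")
  invisible(x)
}

#' Plot observed series, counterfactual forecast and effect estimates
#'
#' Two panels: left, the observed counts with the counterfactual forecast
#' median `exp(mu)` and its Monte Carlo percentile band over the post
#' period; right, per-period effect points (observed minus counterfactual)
#' with UI bars and a zero reference line.
#'
#' @param panel A [half_year_panel()].
#' @param stratum Stratum plotted.
#' @param path The stratum's [forecast_path()].
#' @param effects The stratum's [effect_summary()].
#' @param out PNG file path.
#' @return `out`, invisibly. The plotted numeric arrays are attached as
#'   attribute `plot_data` so tests can verify the figure shows the same
#'   numbers the report contains.
#' @export
plot_fit_and_effects <- function(panel, stratum, path, effects, out) {
  y <- panel_counts(panel, stratum)
  k <- panel$intervention_index
  h <- path$horizon
  if (length(y) != k + h || nrow(effects$per_period) != h) {
    stop("plot_fit_and_effects: panel, forecast and effects lengths disagree",
         call. = FALSE)
  }
  post_idx <- k + seq_len(h)
  band <- cbind(exp(path$log_means + stats::qnorm(0.025) * path$log_ses),
                exp(path$log_means + stats::qnorm(0.975) * path$log_ses))
  pp <- effects$per_period

  grDevices::png(out, width = 1200, height = 500)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  ylim <- range(0, y, band)
  graphics::plot(seq_along(y), y, type = "o", pch = 16, ylim = ylim,
                 xlab = "half-year period", ylab = "injuries",
                 main = paste("Observed and counterfactual,", stratum))
  graphics::polygon(c(post_idx, rev(post_idx)), c(band[, 1], rev(band[, 2])),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(post_idx, path$median_counts, col = "steelblue", lwd = 2)
  graphics::abline(v = k + 0.5, lty = 2)
  graphics::plot(seq_len(h), pp$diff, pch = 16,
                 ylim = range(0, pp$diff_low, pp$diff_high),
                 xlab = "post period", ylab = "observed - counterfactual",
                 main = paste("Per-period effect,", stratum))
  graphics::arrows(seq_len(h), pp$diff_low, seq_len(h), pp$diff_high,
                   angle = 90, code = 3, length = 0.04)
  graphics::abline(h = 0, lty = 2)

  structure(invisible(out),
            plot_data = list(observed = y, forecast = path$median_counts,
                             band = band, effect = pp$diff,
                             effect_low = pp$diff_low,
                             effect_high = pp$diff_high))
}
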
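# printed summary counts of the Odense series (before = 17 periods, after = 10)
odense_counts <- list(
  all = c(before = 1748L, after = 874L),
  private = c(before = 1269L, after = 610L),
  public = c(before = 480L, after = 264L),
  n_pre = 17L, n_post = 10L
)

# deterministic event fixture: 2622 events over the study window with 1748
# dated before 2010-07-01 and 874 on/after; per-period totals are spread as
# evenly as integer division allows.  Stratum composition within each side is
# chosen to respect the one-event discrepancy tolerance (1268 + 480 pre).
make_odense_events <- function() {
  window <- odense_window()
  grid <- bitecast:::half_year_grid(window)
  spread <- function(total, idx) {
    k <- length(idx)
    base <- total %/% k
    extra <- total %% k
    n_per <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    dates <- list()
    for (j in seq_len(k)) {
      # stay inside the period: offsets cycle over the first 150 days
      dates[[j]] <- grid$start[idx[j]] + (seq_len(n_per[j]) - 1L) %% 150L
    }
    do.call(c, dates)
  }
  pre <- 1:17; post <- 18:27
  dates <- c(spread(1268L, pre), spread(480L, pre),
             spread(610L, post), spread(264L, post))
  loc <- c(rep("private", 1268L), rep("public", 480L),
           rep("private", 610L), rep("public", 264L))
  injury_events(dates, loc)
}

# small synthetic panel for structural tests (fast, low counts)
make_small_panel <- function(seed = 42L, n_periods = 15L, k = 9L) {
  cfg <- function(b) synth_config(n_periods = n_periods,
                                  intervention_index = k,
                                  baseline_log_level = log(b))
  simulate_panel(cfg(40), cfg(15), seed = seed)
}

# hand-built arima_fit stub for closed-form residual checks
fake_fit <- function(residuals, d = 0L) {
  structure(list(order = arima_order(0L, d, 0L), ar_coefs = numeric(),
                 ma_coefs = numeric(), constant = NA_real_, sigma2 = 1,
                 residuals = residuals, loglik = 0, converged = TRUE,
                 n = length(residuals), series = residuals, model = NULL),
            class = "arima_fit")
}
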
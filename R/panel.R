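#' Study window for an interrupted time-series analysis
#'
#' Defines the observation window and the intervention date. The window must
#' start on a half-year boundary (January 1 or July 1) and end on the last day
#' of a half-year (June 30 or December 31), so that it spans an integer number
#' of 6-month periods.
#'
#' @param start,end First and last calendar day of the study window
#'   (`Date` or ISO-8601 string).
#' @param intervention_date Date the intervention took effect. Must satisfy
#'   `start < intervention_date <= end`.
#' @return An object of class `study_window`.
#' @examples
#' odense_window()
#' study_window("2002-01-01", "2015-06-30", "2010-06-01")
#' @export
study_window <- function(start, end, intervention_date) {
  start <- as.Date(start)
  end <- as.Date(end)
  intervention_date <- as.Date(intervention_date)
  if (anyNA(c(start, end, intervention_date))) {
    stop("study_window: dates must be valid calendar dates", call. = FALSE)
  }
  if (!(start < intervention_date && intervention_date <= end)) {
    stop("study_window: need start < intervention_date <= end", call. = FALSE)
  }
  sm <- as.integer(format(start, "%m"))
  sd_ <- as.integer(format(start, "%d"))
  if (!(sd_ == 1L && sm %in% c(1L, 7L))) {
    stop("study_window: start must be Jan 1 or Jul 1 (half-year boundary)",
         call. = FALSE)
  }
  em <- as.integer(format(end, "%m"))
  ed <- as.integer(format(end, "%d"))
  if (!((em == 6L && ed == 30L) || (em == 12L && ed == 31L))) {
    stop("study_window: end must be Jun 30 or Dec 31 (half-year boundary)",
         call. = FALSE)
  }
  structure(list(start = start, end = end,
                 intervention_date = intervention_date),
            class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat("Study window:", format(x$start), "to", format(x$end),
      "| intervention:", format(x$intervention_date), "\n")
  invisible(x)
}

#' Default window of the Odense dog-bite series
#'
#' January 1 2002 through June 30 2015, with the Danish breed ban taking
#' effect on June 1 2010. The binning convention (H1 = Jan-Jun) makes 2010H1
#' the last pre-intervention period, giving 17 pre and 10 post half-years.
#'
#' @return A `study_window`.
#' @export
odense_window <- function() {
  study_window("2002-01-01", "2015-06-30", "2010-06-01")
}

#' Construct a table of injury events
#'
#' An event is one emergency-department presentation, carrying only its date
#' and whether it occurred in a private or public space ("unknown" is allowed
#' and counts toward the all-location total but neither stratum).
#'
#' @param date Vector of dates (`Date` or ISO-8601 strings).
#' @param location Character vector, each element one of
#'   `"private"`, `"public"`, `"unknown"`.
#' @return A `data.frame` with columns `date` and `location`, class
#'   `injury_events`.
#' @export
injury_events <- function(date, location) {
  date <- as.Date(date)
  if (anyNA(date)) {
    stop("injury_events: invalid date at row ",
         which(is.na(date))[1L], call. = FALSE)
  }
  location <- as.character(location)
  bad <- !(location %in% c("private", "public", "unknown"))
  if (any(bad)) {
    stop("injury_events: unknown location '", location[which(bad)[1L]],
         "' at row ", which(bad)[1L],
         " (expected private/public/unknown)", call. = FALSE)
  }
  if (length(date) != length(location)) {
    stop("injury_events: date and location lengths differ", call. = FALSE)
  }
  structure(data.frame(date = date, location = location,
                       stringsAsFactors = FALSE),
            class = c("injury_events", "data.frame"))
}

# period grid covering a window: one row per half-year, H1 = Jan-Jun, H2 = Jul-Dec
half_year_grid <- function(window) {
  sy <- as.integer(format(window$start, "%Y"))
  ey <- as.integer(format(window$end, "%Y"))
  grid <- expand.grid(half = c("H1", "H2"), year = sy:ey,
                      stringsAsFactors = FALSE)[, c("year", "half")]
  grid$start <- as.Date(ifelse(grid$half == "H1",
                               paste0(grid$year, "-01-01"),
                               paste0(grid$year, "-07-01")))
  grid$end <- as.Date(ifelse(grid$half == "H1",
                             paste0(grid$year, "-06-30"),
                             paste0(grid$year, "-12-31")))
  grid <- grid[grid$start >= window$start & grid$end <= window$end, ]
  rownames(grid) <- NULL
  grid
}

#' Construct a stratified half-year count panel
#'
#' Low-level constructor; most users will call [bin_events()] or
#' [simulate_panel()] instead. `intervention_index` is the number of
#' pre-intervention periods, i.e. the (1-based) index of the last period
#' before the intervention; the first post period is `intervention_index + 1`.
#'
#' @param periods Data frame with columns `year` and `half` (`"H1"`/`"H2"`).
#' @param counts_private,counts_public,counts_all Integer count vectors, one
#'   entry per period. `counts_all` defaults to the sum of the two strata.
#' @param intervention_index Number of pre-intervention periods; must satisfy
#'   `0 < intervention_index < nrow(periods)`.
#' @return An object of class `half_year_panel`.
#' @export
half_year_panel <- function(periods, counts_private, counts_public,
                            counts_all = counts_private + counts_public,
                            intervention_index) {
  n <- nrow(periods)
  stopifnot(is.data.frame(periods), all(c("year", "half") %in% names(periods)))
  for (v in list(counts_private, counts_public, counts_all)) {
    if (length(v) != n) {
      stop("half_year_panel: count vector length != number of periods",
           call. = FALSE)
    }
    if (any(v < 0) || any(v != round(v))) {
      stop("half_year_panel: counts must be non-negative integers",
           call. = FALSE)
    }
  }
  if (any(counts_all < counts_private + counts_public)) {
    stop("half_year_panel: counts_all below sum of strata (conservation)",
         call. = FALSE)
  }
  intervention_index <- as.integer(intervention_index)
  if (!(intervention_index > 0L && intervention_index < n)) {
    stop("half_year_panel: intervention_index must lie strictly inside ",
         "the period range", call. = FALSE)
  }
  structure(list(
    periods = data.frame(year = as.integer(periods$year),
                         half = as.character(periods$half),
                         stringsAsFactors = FALSE),
    counts_private = as.integer(counts_private),
    counts_public = as.integer(counts_public),
    counts_all = as.integer(counts_all),
    intervention_index = intervention_index
  ), class = "half_year_panel")
}

#' @export
print.half_year_panel <- function(x, ...) {
  n <- length(x$counts_all)
  cat("Half-year count panel:", n, "periods (",
      x$periods$year[1], x$periods$half[1], "to",
      x$periods$year[n], x$periods$half[n], ")\n")
  cat("  pre periods:", x$intervention_index,
      "| post periods:", n - x$intervention_index, "\n")
  cat("  totals: all", sum(x$counts_all),
      "| private", sum(x$counts_private),
      "| public", sum(x$counts_public), "\n")
  invisible(x)
}

#' Bin injury events into a stratified half-year panel
#'
#' Each event is assigned to the half-year containing its date
#' (H1 = Jan 1-Jun 30, H2 = Jul 1-Dec 31). The intervention boundary is the
#' half-year boundary nearest to `window$intervention_date` (ties go to the
#' later boundary), so a June 1 intervention makes H1 of that year the last
#' pre period. Events outside the window are rejected, not silently dropped:
#' their number is recorded in the `n_rejected` attribute and reported via a
#' warning.
#'
#' @param events An [injury_events()] table (or any data frame with `date`
#'   and `location` columns).
#' @param window A [study_window()].
#' @return A [half_year_panel()] with attribute `n_rejected`.
#' @export
bin_events <- function(events, window) {
  stopifnot(inherits(window, "study_window"))
  if (!all(c("date", "location") %in% names(events))) {
    stop("bin_events: events need 'date' and 'location' columns",
         call. = FALSE)
  }
  events <- injury_events(events$date, events$location)
  grid <- half_year_grid(window)

  inside <- events$date >= window$start & events$date <= window$end
  n_rejected <- sum(!inside)
  if (n_rejected > 0L) {
    warning("bin_events: rejected ", n_rejected,
            " event(s) outside the study window", call. = FALSE)
  }
  ev <- events[inside, , drop = FALSE]

  # period index: findInterval over period starts partitions the window
  idx <- findInterval(as.numeric(ev$date), as.numeric(grid$start))
  tab <- function(loc) {
    tabulate(idx[ev$location %in% loc], nbins = nrow(grid))
  }
  counts_private <- tab("private")
  counts_public <- tab("public")
  counts_all <- tab(c("private", "public", "unknown"))

  boundary <- nearest_half_year_boundary(window$intervention_date)
  intervention_index <- sum(grid$start < boundary)
  panel <- half_year_panel(grid[, c("year", "half")],
                           counts_private, counts_public, counts_all,
                           intervention_index)
  attr(panel, "n_rejected") <- n_rejected
  panel
}

# nearest Jan 1 / Jul 1 boundary; equidistant dates round to the later one
nearest_half_year_boundary <- function(date) {
  y <- as.integer(format(date, "%Y"))
  cand <- as.Date(c(paste0(y, "-01-01"), paste0(y, "-07-01"),
                    paste0(y + 1L, "-01-01")))
  d <- abs(as.numeric(date - cand))
  cand[max(which(d == min(d)))]
}

#' Split a panel's count series at the intervention
#'
#' @param panel A [half_year_panel()].
#' @param stratum One of `"all"`, `"private"`, `"public"`.
#' @return A list with integer vectors `pre` (length `intervention_index`)
#'   and `post` (the remaining periods).
#' @export
split_pre_post <- function(panel, stratum = c("all", "private", "public")) {
  stopifnot(inherits(panel, "half_year_panel"))
  stratum <- match.arg(stratum)
  y <- panel_counts(panel, stratum)
  k <- panel$intervention_index
  list(pre = y[seq_len(k)], post = y[-seq_len(k)])
}

#' Extract one stratum's full count series
#'
#' @inheritParams split_pre_post
#' @return Integer vector of counts, one per period.
#' @export
panel_counts <- function(panel, stratum = c("all", "private", "public")) {
  stratum <- match.arg(stratum)
  switch(stratum,
         all = panel$counts_all,
         private = panel$counts_private,
         public = panel$counts_public)
}

#' Read an events CSV
#'
#' Expects header columns `date` (ISO-8601) and `location`
#' (private/public/unknown). Malformed rows raise an error naming the row.
#'
#' @param path File path.
#' @return An [injury_events()] table.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("date", "location") %in% names(df))) {
    stop("read_events_csv: need 'date' and 'location' columns", call. = FALSE)
  }
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(dates)) {
    stop("read_events_csv: malformed date '", df$date[which(is.na(dates))[1L]],
         "' at row ", which(is.na(dates))[1L], call. = FALSE)
  }
  injury_events(dates, df$location)
}

#' Write / read a half-year panel as CSV
#'
#' The format has columns `year,half,private,public,all` plus an
#' `intervention` column holding 0 (pre) or 1 (post), so the file is
#' self-describing and round-trips exactly.
#'
#' @param panel A [half_year_panel()].
#' @param path File path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a [half_year_panel()].
#' @export
write_panel_csv <- function(panel, path) {
  stopifnot(inherits(panel, "half_year_panel"))
  n <- length(panel$counts_all)
  df <- data.frame(year = panel$periods$year, half = panel$periods$half,
                   private = panel$counts_private,
                   public = panel$counts_public,
                   all = panel$counts_all,
                   intervention = as.integer(seq_len(n) >
                                               panel$intervention_index))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "half", "private", "public", "all", "intervention")
  if (!all(need %in% names(df))) {
    stop("read_panel_csv: need columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  half_year_panel(df[, c("year", "half")], df$private, df$public, df$all,
                  intervention_index = sum(df$intervention == 0L))
}
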
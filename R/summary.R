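#' Per-drone activity summaries
#'
#' One row per tag present in the span table.  A "flight" is a completed
#' departure-arrival pair (an uncensored outside span); a final departure
#' with no return is counted separately in \code{n_censored_departures}.
#' Morning/afternoon departure counts split every departure (the start of any
#' non-left-censored outside span) at the 12:00 noon cutoff, so
#' \code{morning_departures + afternoon_departures} equals the tag's total
#' departures.  Drones with zero events do not appear here; they are
#' accounted for by \code{\link{cohort_report}}.
#'
#' @param cspans classified spans from \code{\link{classify_spans}}.
#' @param reads optional raw read table; supplies \code{n_reads_total},
#'   \code{first_seen}, \code{last_seen} (otherwise taken from span times).
#' @return data.frame with one row per tag: flight counts, period counts,
#'   \code{active_both_periods}, per-category counts (\code{n_<category>}),
#'   and \code{max_inside_days} / \code{max_outside_days} (calendar-day
#'   convention \code{floor(d / 24 h) + 1}; 0 when no such span).
#' @export
summarize_drones <- function(cspans, reads = NULL) {
  tags <- sort(unique(cspans$tag_id))
  rows <- lapply(tags, function(tg) {
    sp <- cspans[cspans$tag_id == tg, , drop = FALSE]
    outs <- sp[sp$location == "outside", , drop = FALSE]
    deps <- outs[outs$censored != "left", , drop = FALSE]
    completed <- outs[outs$censored == "none", , drop = FALSE]
    ins <- sp[sp$location == "inside" & sp$censored == "none", , drop = FALSE]
    morning <- sum(is_morning(deps$start))
    cat_counts <- table(factor(sp$category, levels = .behavior_levels))
    day_of <- function(d) if (length(d) == 0L) 0L
                          else as.integer(floor(max(d) / 1440)) + 1L
    times <- c(sp$start, sp$end)
    times <- times[!is.na(times)]
    if (!is.null(reads)) {
      rt <- reads$timestamp[reads$tag_id == tg]
      n_reads <- length(rt)
      if (n_reads > 0L) times <- rt
    } else n_reads <- NA_integer_
    out <- data.frame(
      tag_id = tg,
      n_flights_completed = nrow(completed),
      n_censored_departures = sum(outs$censored == "right"),
      n_reads_total = n_reads,
      first_seen = min(times),
      last_seen = max(times),
      morning_departures = morning,
      afternoon_departures = nrow(deps) - morning,
      active_both_periods = morning > 0L && (nrow(deps) - morning) > 0L,
      max_inside_days = day_of(ins$duration_min),
      max_outside_days = day_of(completed$duration_min),
      stringsAsFactors = FALSE)
    for (nm in names(cat_counts))
      out[[paste0("n_", nm)]] <- as.integer(cat_counts[[nm]])
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) res <- data.frame(tag_id = character(0))
  rownames(res) <- NULL
  res
}

#' Cohort detection accounting
#'
#' Splits the tagged cohort into never-detected tags (zero reads), single-read
#' tags, and tags with two or more reads, with percentages over the full
#' cohort.
#'
#' @param reads raw read table for the whole run.
#' @param n_tagged size of the tagged cohort (denominator), including drones
#'   that never produced a read.
#' @return list with counts and percentages: \code{n_tagged},
#'   \code{n_detected}, \code{n_never_detected}, \code{pct_never_detected},
#'   \code{n_single_read}, \code{pct_single_read}.
#' @export
cohort_report <- function(reads, n_tagged) {
  if (is.null(n_tagged) || n_tagged < 1)
    stop("n_tagged must be a positive cohort size", call. = FALSE)
  counts <- table(reads$tag_id)
  n_detected <- length(counts)
  if (n_detected > n_tagged)
    stop("more distinct tags in reads than n_tagged", call. = FALSE)
  n_never <- as.integer(n_tagged - n_detected)
  n_single <- sum(counts == 1L)
  list(n_tagged = as.integer(n_tagged),
       n_detected = n_detected,
       n_never_detected = n_never,
       pct_never_detected = 100 * n_never / n_tagged,
       n_single_read = as.integer(n_single),
       pct_single_read = 100 * n_single / n_tagged)
}

#' Morning and both-period activity fractions
#'
#' Fraction of the tagged cohort recorded leaving the hive in the morning
#' (before 12:00) at least once, and fraction active in both the morning and
#' the afternoon.  The denominator is the full tagged cohort, including
#' never-detected drones, so \code{both_fraction <= morning_fraction} always.
#'
#' @param summaries data.frame from \code{\link{summarize_drones}}.
#' @param n_tagged cohort size (denominator); a non-positive value is an
#'   error.
#' @return list(morning_fraction, both_fraction).
#' @export
period_fractions <- function(summaries, n_tagged) {
  if (is.null(n_tagged) || n_tagged < 1)
    stop("n_tagged must be a positive cohort size", call. = FALSE)
  morning <- sum(summaries$morning_departures > 0)
  both <- sum(summaries$active_both_periods)
  list(morning_fraction = morning / n_tagged,
       both_fraction = both / n_tagged)
}

#' Hour-of-day by duration-class flight profile
#'
#' Bins every completed flight by its departure hour (0-23) and duration
#' class (<=3 min, 3-10 min, 10-60 min, >60 min; lower-exclusive,
#' upper-inclusive).  The full 24 x 4 grid is returned zero-filled, so the
#' grand total equals the number of completed flights.
#'
#' @param cspans classified spans from \code{\link{classify_spans}}.
#' @return data.frame \code{hour}, \code{duration_class}, \code{n} (long
#'   format, 96 rows).
#' @export
hourly_profile <- function(cspans) {
  fl <- cspans[cspans$location == "outside" & cspans$censored == "none", ,
               drop = FALSE]
  hour <- floor(.clock_hour(fl$start))
  klass <- cut(fl$duration_min, c(0, 3, 10, 60, Inf),
               labels = .duration_class_levels, right = TRUE)
  tab <- table(factor(hour, levels = 0:23),
               factor(klass, levels = .duration_class_levels))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("hour", "duration_class", "n")
  out$hour <- as.integer(as.character(out$hour))
  out
}

#' Default departure-time group windows
#'
#' Clock-hour windows (half-open, decimal hours) for the four recurring
#' departure-time groups: dawn (~3 a.m.), early morning (~6 a.m.), midday
#' (~11 a.m.-noon) and late afternoon (~5 p.m.).
#'
#' @return named list of \code{c(start_hour, end_hour)} pairs.
#' @export
departure_windows <- function() {
  list(dawn = c(2, 4), early_morning = c(5, 8),
       midday = c(10, 13), late_afternoon = c(16, 18))
}

#' Assign departures to clock-time groups
#'
#' Each departure event is assigned to at most one group window; departures
#' outside every window are labelled \code{"ungrouped"}.  Overlapping windows
#' are a hard error.
#'
#' @param events event data.frame; only rows with \code{kind == "departure"}
#'   are assigned (others get NA).
#' @param windows named list of \code{c(start_hour, end_hour)} half-open
#'   clock-hour intervals, as \code{\link{departure_windows}}.
#' @return \code{events} with an added \code{group} column.
#' @export
departure_groups <- function(events, windows = departure_windows()) {
  if (length(windows) > 1L) {
    m <- do.call(rbind, windows)
    ord <- order(m[, 1])
    if (any(m[ord, 2][-length(windows)] > m[ord, 1][-1]))
      stop("departure-time windows overlap", call. = FALSE)
  }
  h <- .clock_hour(events$timestamp)
  group <- rep(NA_character_, nrow(events))
  dep <- events$kind == "departure"
  group[dep] <- "ungrouped"
  for (nm in names(windows)) {
    w <- windows[[nm]]
    group[dep & h >= w[1] & h < w[2]] <- nm
  }
  events$group <- group
  events
}

#' Flag unusual long morning-departure flights
#'
#' Flags completed flights longer than 60 min that departed in the morning
#' (before 12:00) and arrived back at afternoon peak time (clock time in
#' [14:00, 18:00)) -- the signature of drones leaving at dawn or during the
#' morning and returning with the main afternoon traffic.
#'
#' @param cspans classified spans from \code{\link{classify_spans}}.
#' @return the flagged subset of completed outside spans.
#' @export
unusual_activity <- function(cspans) {
  fl <- cspans[cspans$location == "outside" & cspans$censored == "none", ,
               drop = FALSE]
  arr_h <- .clock_hour(fl$end)
  keep <- fl$duration_min > 60 & is_morning(fl$start) &
    arr_h >= 14 & arr_h < 18
  out <- fl[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Daily activity series
#'
#' One row per calendar date of the observation window (zero-filled for
#' inactive days).  A flight is attributed to the date of its departure; a
#' day's mean flight duration is NA when it had no flights.
#'
#' @param cspans classified spans from \code{\link{classify_spans}}.
#' @param window_start,window_end Date bounds of the series; default to the
#'   range of departure dates present.
#' @return data.frame \code{date}, \code{n_flights}, \code{n_active_drones},
#'   \code{mean_flight_duration}.
#' @export
daily_series <- function(cspans, window_start = NULL, window_end = NULL) {
  fl <- cspans[cspans$location == "outside" & cspans$censored == "none", ,
               drop = FALSE]
  dep_date <- as.Date(fl$start, tz = .TZ)
  if (is.null(window_start))
    window_start <- if (nrow(fl)) min(dep_date) else Sys.Date()
  if (is.null(window_end))
    window_end <- if (nrow(fl)) max(dep_date) else Sys.Date()
  dates <- seq(as.Date(window_start), as.Date(window_end), by = "day")
  n_flights <- as.integer(table(factor(as.character(dep_date),
                                       levels = as.character(dates))))
  active <- vapply(dates, function(d)
    length(unique(fl$tag_id[dep_date == d])), integer(1))
  mean_dur <- vapply(dates, function(d) {
    x <- fl$duration_min[dep_date == d]
    if (length(x) == 0L) NA_real_ else mean(x)
  }, numeric(1))
  data.frame(date = dates, n_flights = n_flights,
             n_active_drones = active, mean_flight_duration = mean_dur,
             stringsAsFactors = FALSE)
}
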
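#' Behavior classification thresholds
#'
#' Duration thresholds (minutes) separating the behavior categories, and the
#' convention for counting days away.  Defaults: exit/entry up to 3 min,
#' orientation ("short mission") up to 10 min, DCA scouting up to 10 h,
#' anything longer an extended absence; inside stays over 30 min are resting;
#' spans shorter than 1 s are unresolved.
#'
#' @param exit_entry_max,short_mission_max,scouting_max,resting_min thresholds
#'   in minutes; must be strictly increasing where applicable.
#' @param min_span_s minimum resolvable span length in seconds.
#' @return named list of class \code{behavior_thresholds}.
#' @export
behavior_thresholds <- function(exit_entry_max = 3, short_mission_max = 10,
                                scouting_max = 600, resting_min = 30,
                                min_span_s = 1) {
  if (!(exit_entry_max < short_mission_max && short_mission_max < scouting_max))
    stop("thresholds must be strictly increasing", call. = FALSE)
  structure(list(exit_entry_max = exit_entry_max,
                 short_mission_max = short_mission_max,
                 scouting_max = scouting_max,
                 resting_min = resting_min,
                 min_span_s = min_span_s),
            class = "behavior_thresholds")
}

#' Build inside/outside spans from the event stream
#'
#' The time a drone spent outside the hive is the span between a departure
#' and the subsequent arrival; the time inside is the span between an arrival
#' and the renewed departure.  Censoring: a tag's leading arrival opens a
#' left-censored outside span (the departure predates the record); a trailing
#' departure opens a right-censored outside span (the drone never returned);
#' two same-kind consecutive events bound a "broken" span (its complement
#' event was missed) which is excluded from duration statistics.
#'
#' @param events event data.frame from \code{\link{detect_events}},
#'   chronological within each tag (out-of-order input is a hard error).
#' @param window_start,window_end optional POSIXct bounds of the observation
#'   window, used as the open ends of censored spans (NA otherwise).
#' @return data.frame with columns \code{tag_id}, \code{location}
#'   ("outside"/"inside"), \code{start}, \code{end}, \code{duration_min},
#'   \code{censored} ("none"/"left"/"right"/"broken").  Durations of censored
#'   spans are NA.
#' @export
build_spans <- function(events, window_start = NULL, window_end = NULL) {
  ws <- if (is.null(window_start)) as.POSIXct(NA, tz = .TZ)
        else .as_time(window_start)
  we <- if (is.null(window_end)) as.POSIXct(NA, tz = .TZ)
        else .as_time(window_end)
  empty <- data.frame(tag_id = character(0), location = character(0),
                      start = as.POSIXct(character(0), tz = .TZ),
                      end = as.POSIXct(character(0), tz = .TZ),
                      duration_min = numeric(0), censored = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(events) == 0L) return(empty)

  bad <- tapply(as.numeric(events$timestamp), events$tag_id, is.unsorted)
  if (any(bad))
    stop("events out of chronological order for tag(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)

  out <- lapply(split(events, events$tag_id), function(ev) {
    n <- nrow(ev)
    loc <- character(0); st <- numeric(0); en <- numeric(0)
    cen <- character(0)
    tt <- as.numeric(ev$timestamp)
    if (ev$kind[1L] == "arrival") {           # left-censored outside span
      loc <- "outside"; st <- as.numeric(ws); en <- tt[1L]; cen <- "left"
    }
    if (n > 1L) {
      for (j in seq_len(n - 1L)) {
        a <- ev$kind[j]; b <- ev$kind[j + 1L]
        loc <- c(loc, if (a == "departure") "outside" else "inside")
        st <- c(st, tt[j]); en <- c(en, tt[j + 1L])
        cen <- c(cen, if (a == b) "broken" else "none")
      }
    }
    if (ev$kind[n] == "departure") {          # right-censored outside span
      loc <- c(loc, "outside"); st <- c(st, tt[n])
      en <- c(en, as.numeric(we)); cen <- c(cen, "right")
    }
    dur <- ifelse(cen == "none", (en - st) / 60, NA_real_)
    data.frame(tag_id = ev$tag_id[1L], location = loc,
               start = as.POSIXct(st, origin = "1970-01-01", tz = .TZ),
               end = as.POSIXct(en, origin = "1970-01-01", tz = .TZ),
               duration_min = dur, censored = cen, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(list(empty), out))
  rownames(res) <- NULL
  if (any(res$duration_min <= 0, na.rm = TRUE))
    stop("non-positive span duration: events share a timestamp",
         call. = FALSE)
  res
}

#' Assign behavior categories to spans
#'
#' Duration-based classification of inside/outside spans:
#' \itemize{
#'   \item outside, d <= 3 min: \code{exit_entry} (defecation, bearding,
#'     popping out to re-enter and feed);
#'   \item outside, 3 < d <= 10 min: \code{short_mission} (orientation
#'     flight);
#'   \item outside, 10 min < d <= 10 h: \code{scouting} (searching for or
#'     staying at a drone congregation area);
#'   \item outside, d > 10 h: \code{extended_absence}, with
#'     \code{days_away = floor(d / 24 h) + 1} so a 24-48 h absence reads as
#'     "2 days";
#'   \item inside, d <= 30 min: \code{brief_inside};
#'   \item inside, d > 30 min: \code{resting} (spans beyond 10 h keep the
#'     category but set \code{long_stay});
#'   \item right-censored outside: \code{departed_drone} (last detection of
#'     the individual);
#'   \item broken or left-censored spans, and spans below 1 s:
#'     \code{unresolved}.
#' }
#' Interval edges are lower-exclusive / upper-inclusive throughout.
#'
#' @param spans data.frame from \code{\link{build_spans}}.
#' @param thresholds a \code{\link{behavior_thresholds}} object.
#' @return \code{spans} with added columns \code{category} (factor over the
#'   eight categories), \code{days_away} (integer, extended absences only),
#'   \code{long_stay} (logical, resting spans beyond the 10 h table bound).
#' @export
classify_spans <- function(spans, thresholds = behavior_thresholds()) {
  if (any(spans$duration_min < 0, na.rm = TRUE))
    stop("negative span duration", call. = FALSE)
  d <- spans$duration_min
  n <- nrow(spans)
  cat <- rep("unresolved", n)
  days_away <- rep(NA_integer_, n)
  long_stay <- rep(FALSE, n)

  outside <- spans$location == "outside"
  inside <- spans$location == "inside"
  none <- spans$censored == "none"

  cat[outside & spans$censored == "right"] <- "departed_drone"

  ok <- outside & none & d >= thresholds$min_span_s / 60
  cat[ok & d <= thresholds$exit_entry_max] <- "exit_entry"
  cat[ok & d > thresholds$exit_entry_max &
        d <= thresholds$short_mission_max] <- "short_mission"
  cat[ok & d > thresholds$short_mission_max &
        d <= thresholds$scouting_max] <- "scouting"
  ext <- ok & d > thresholds$scouting_max
  cat[ext] <- "extended_absence"
  days_away[ext] <- as.integer(floor(d[ext] / 1440)) + 1L

  iok <- inside & none & d >= thresholds$min_span_s / 60
  cat[iok & d <= thresholds$resting_min] <- "brief_inside"
  rest <- iok & d > thresholds$resting_min
  cat[rest] <- "resting"
  long_stay[rest & d > thresholds$scouting_max] <- TRUE

  spans$category <- factor(cat, levels = .behavior_levels)
  spans$days_away <- days_away
  spans$long_stay <- long_stay
  spans
}
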
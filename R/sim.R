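#' Simulator configuration
#'
#' Builds and validates the parameter set for the agent-based entrance-traffic
#' simulator.  Defaults reproduce the monitored cohort: 200 tagged drones
#' watched over a 45-day spring mating-season window, 8% of tags never read,
#' 10% read exactly once, and completed flights distributed over four duration
#' classes (<=3 min, 3-10 min, 10-60 min, >60 min) with the 3-10 min
#' orientation-flight class dominant (76.2% of flights).
#'
#' @param n_drones number of tagged drones in the cohort.
#' @param start_date,end_date observation window (Date or "YYYY-MM-DD");
#'   the window is inclusive of both days.
#' @param p_never_detected probability a tagged drone yields zero reads
#'   (tag failure, immediate loss, ...).
#' @param p_single_read probability a tagged drone yields exactly one stray
#'   read and is never seen again.
#' @param behavior_mix named probabilities over the four outside-span duration
#'   classes \code{under_3min}, \code{3_to_10min}, \code{10_to_60min},
#'   \code{over_60min}.  Must sum to 1 (within 1e-6).  The default is the
#'   observed flight-duration mix renormalised to sum to exactly 1.
#' @param afternoon_peak_hour clock hour of the modal (afternoon) departure.
#' @param morning_active_fraction fraction of the tagged cohort recorded
#'   leaving the hive before 12:00 at least once.
#' @param both_period_fraction fraction of the tagged cohort with at least one
#'   morning and one afternoon departure.  Must not exceed
#'   \code{morning_active_fraction}.
#' @param p_permanent_departure per-flight probability, for flights of the
#'   scouting class or longer, that the drone never returns (mating, predation,
#'   disorientation).
#' @param p_drift probability that an over-60-min flight extends into a
#'   1-3 day absence (drifting to another colony or staying afield).
#' @param p_long_rest per-day probability that a drone stays inside for
#'   1-4 days without flying.
#' @param p_read per-antenna-crossing detection probability.
#' @param p_spurious expected number of duplicate/stray reads per real read.
#' @param zero_activity_dates dates (Date or "YYYY-MM-DD") with no flights at
#'   all, emulating weather shutdown days.
#' @param mean_total_flights target mean number of flights per flying drone
#'   over the whole window.
#' @param flight_rate_shape gamma shape for between-drone heterogeneity of the
#'   daily flight rate; small values give "few drones with many flights and
#'   many drones with few flights".
#' @param departure_weights mixture weights of the four departure-time
#'   components (dawn ~03:00, early morning ~06:30, mid morning ~11:00,
#'   afternoon ~\code{afternoon_peak_hour}), used for drones allowed to fly in
#'   both periods; renormalised over the allowed subset otherwise.
#' @param morning_rate_factor multiplier on the flight rate of morning-only
#'   drones (these drones make few, repeated morning sorties).
#' @param seed integer RNG seed; one stream drawn from this seed governs every
#'   stochastic choice, so runs are bit-reproducible.
#' @return an object of class \code{sim_config} (a validated named list).
#' @seealso \code{\link{simulate_traffic}}, \code{\link{simulate_weather}}
#' @export
sim_config <- function(n_drones = 200L,
                       start_date = "2017-10-15",
                       end_date = "2017-11-28",
                       p_never_detected = 0.08,
                       p_single_read = 0.10,
                       behavior_mix = c(under_3min = 0.073,
                                        `3_to_10min` = 0.7622,
                                        `10_to_60min` = 0.124,
                                        over_60min = 0.04) / 0.9992,
                       afternoon_peak_hour = 15,
                       morning_active_fraction = 0.215,
                       both_period_fraction = 0.16,
                       p_permanent_departure = 0.01,
                       p_drift = 0.15,
                       p_long_rest = 0.01,
                       p_read = 1.0,
                       p_spurious = 0.002,
                       zero_activity_dates = c("2017-10-17", "2017-10-18",
                                               "2017-11-03", "2017-11-04"),
                       mean_total_flights = 14.58,
                       flight_rate_shape = 1.0,
                       departure_weights = c(dawn = 0.04, early_morning = 0.07,
                                             midmorning = 0.09,
                                             afternoon = 0.80),
                       morning_rate_factor = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_drones = as.integer(n_drones),
    start_date = as.Date(start_date),
    end_date = as.Date(end_date),
    p_never_detected = p_never_detected,
    p_single_read = p_single_read,
    behavior_mix = behavior_mix,
    afternoon_peak_hour = afternoon_peak_hour,
    morning_active_fraction = morning_active_fraction,
    both_period_fraction = both_period_fraction,
    p_permanent_departure = p_permanent_departure,
    p_drift = p_drift,
    p_long_rest = p_long_rest,
    p_read = p_read,
    p_spurious = p_spurious,
    zero_activity_dates = as.Date(zero_activity_dates),
    mean_total_flights = mean_total_flights,
    flight_rate_shape = flight_rate_shape,
    departure_weights = departure_weights,
    morning_rate_factor = morning_rate_factor,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config a \code{sim_config} object.
#' @export
validate_sim_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_drones < 1L)
    stop("n_drones must be >= 1", call. = FALSE)
  if (is.na(config$start_date) || is.na(config$end_date))
    stop("start_date and end_date must be valid dates", call. = FALSE)
  if (config$end_date <= config$start_date)
    stop("end_date must be after start_date", call. = FALSE)
  probs <- c(p_never_detected = config$p_never_detected,
             p_single_read = config$p_single_read,
             morning_active_fraction = config$morning_active_fraction,
             both_period_fraction = config$both_period_fraction,
             p_permanent_departure = config$p_permanent_departure,
             p_drift = config$p_drift,
             p_long_rest = config$p_long_rest,
             p_read = config$p_read)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stop("probabilities outside [0,1]: ",
         paste(names(probs)[bad], collapse = ", "), call. = FALSE)
  if (config$p_spurious < 0)
    stop("p_spurious must be >= 0", call. = FALSE)
  mix <- config$behavior_mix
  if (length(mix) != 4L || is.null(names(mix)) ||
      !setequal(names(mix), .duration_class_levels))
    stop("behavior_mix must be named over the four duration classes",
         call. = FALSE)
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-6)
    stop("behavior_mix must be nonnegative and sum to 1", call. = FALSE)
  if (config$p_never_detected + config$p_single_read >= 1)
    stop("p_never_detected + p_single_read must be < 1", call. = FALSE)
  if (config$both_period_fraction > config$morning_active_fraction + 1e-12)
    stop("both_period_fraction cannot exceed morning_active_fraction",
         call. = FALSE)
  invisible(config)
}

# departure-time mixture components (clock hours); the midmorning component is
# truncated strictly below noon so morning/afternoon membership is exact
.departure_components <- function(peak_hour) {
  data.frame(
    name = c("dawn", "early_morning", "midmorning", "afternoon"),
    mean = c(3, 6.5, 11, peak_hour),
    sd   = c(0.7, 1.2, 0.8, 1.5),
    lo   = c(0.3, 5.0, 9.5, 12.01),
    hi   = c(5.0, 9.5, 11.99, 21.0)
  )
}

# truncated-normal draw by rejection (ranges are wide, acceptance is high)
.rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:200) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x < hi) return(x)
  }
  stats::runif(1, lo, hi)
}

.draw_hour <- function(comps, weights) {
  k <- sample.int(nrow(comps), 1L, prob = weights)
  .rtruncnorm1(comps$mean[k], comps$sd[k], comps$lo[k], comps$hi[k])
}

# duration in whole seconds for a sampled class; interiors avoid the
# classification thresholds so noiseless recovery is boundary-free
.draw_duration_s <- function(class_idx, p_drift) {
  dur_min <- switch(class_idx,
    stats::runif(1, 0.15, 2.9),        # under_3min
    stats::runif(1, 3.2, 9.8),         # 3_to_10min
    stats::runif(1, 10.5, 58),         # 10_to_60min
    {                                  # over_60min
      if (stats::runif(1) < p_drift)
        stats::runif(1, 1.05, 3) * 1440          # 1-3 day drift
      else
        62 + min(stats::rexp(1, 1 / 100), 718)   # up to ~13 h
    })
  max(9L, as.integer(round(dur_min * 60)))
}

#' Simulate drone entrance traffic and the RFID read stream
#'
#' Agent-based generator.  Each tagged drone is assigned a fate (never
#' detected, single stray read, or flying), a period profile (morning-only,
#' afternoon-only, or both, calibrated so the expected cohort fractions match
#' \code{morning_active_fraction} and \code{both_period_fraction}), and an
#' individual daily flight rate (gamma-heterogeneous, producing few drones
#' with many flights and many drones with few).  Flights are scheduled day by
#' day from a four-component truncated-normal clock-time mixture; each flight
#' draws a duration class from \code{behavior_mix}.  Every true crossing emits
#' its grammar reads -- (A, B, B) for a departure, (B, A, A) for an arrival --
#' each read retained with probability \code{p_read}; spurious duplicate reads
#' are injected at rate \code{p_spurious} per real read.  No departure is ever
#' scheduled on a \code{zero_activity_dates} day.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return a list with elements
#'   \describe{
#'     \item{reads}{data.frame of raw reads: \code{tag_id}, \code{timestamp}
#'       (POSIXct, 1 s resolution), \code{sensor} ("A"/"B"), sorted by
#'       (tag_id, timestamp).}
#'     \item{truth}{data.frame of ground-truth events: \code{tag_id},
#'       \code{kind} ("departure"/"arrival"), \code{true_time},
#'       \code{behavior_class} (duration class of the flight).  Per tag,
#'       events strictly alternate starting with a departure; a final
#'       unpaired departure occurs iff the drone permanently departed.}
#'     \item{cohort}{data.frame with one row per tagged drone: \code{tag_id},
#'       \code{fate} ("never_detected"/"single_read"/"flyer"),
#'       \code{morning_active}, \code{afternoon_active}.}
#'   }
#' @export
simulate_traffic <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  days <- seq(config$start_date, config$end_date, by = "day")
  n_days <- length(days)
  zero_days <- config$zero_activity_dates
  flight_days <- days[!days %in% zero_days]
  if (length(flight_days) == 0L)
    stop("every day in the window is a zero-activity day", call. = FALSE)
  tags <- sprintf("D%04d", seq_len(config$n_drones))
  p_fly <- 1 - config$p_never_detected - config$p_single_read
  fate <- sample(c("never_detected", "single_read", "flyer"),
                 config$n_drones, replace = TRUE,
                 prob = c(config$p_never_detected, config$p_single_read,
                          p_fly))
  p_morning <- if (p_fly > 0) min(1, config$morning_active_fraction / p_fly)
               else 0
  p_both_given_m <- if (config$morning_active_fraction > 0)
    min(1, config$both_period_fraction / config$morning_active_fraction)
  else 0

  comps <- .departure_components(config$afternoon_peak_hour)
  w_all <- config$departure_weights
  mean_daily <- max(0.01, (config$mean_total_flights - 1) / n_days)
  mix <- config$behavior_mix[.duration_class_levels]

  t_tag <- character(0); t_kind <- character(0)
  t_time <- numeric(0); t_class <- character(0)
  morning_active <- logical(config$n_drones)
  afternoon_active <- logical(config$n_drones)

  for (d in seq_len(config$n_drones)) {
    if (fate[d] != "flyer") next
    m_act <- stats::runif(1) < p_morning
    a_act <- if (m_act) stats::runif(1) < p_both_given_m else TRUE
    morning_active[d] <- m_act
    afternoon_active[d] <- a_act

    allowed <- which(c(m_act, m_act, m_act, a_act))
    rate <- stats::rgamma(1, shape = config$flight_rate_shape,
                          rate = config$flight_rate_shape / mean_daily)
    if (m_act && !a_act) rate <- rate * config$morning_rate_factor

    pending_morning <- m_act
    pending_afternoon <- m_act && a_act

    dep_t <- numeric(0); arr_t <- numeric(0); cls <- integer(0)
    alive <- TRUE
    avail <- -Inf   # epoch seconds after which the drone is inside again
    i_day <- 1L
    while (i_day <= n_days && alive) {
      day <- days[i_day]
      if (day %in% zero_days) { i_day <- i_day + 1L; next }
      if (stats::runif(1) < config$p_long_rest) {
        i_day <- i_day + sample(1:4, 1L)
        next
      }
      day0 <- as.numeric(as.POSIXct(paste0(format(day), " 00:00:00"),
                                    tz = .TZ))
      nf <- stats::rpois(1, rate)
      hrs <- numeric(0)
      if (nf > 0)
        hrs <- vapply(seq_len(nf), function(i)
          .draw_hour(comps[allowed, ], w_all[allowed]), numeric(1))
      # forced flights guarantee the drone realises its period profile
      if (pending_morning) {
        hrs <- c(hrs, .draw_hour(comps[1:3, ], w_all[1:3]))
        pending_morning <- FALSE
      }
      if (pending_afternoon) {
        hrs <- c(hrs, .rtruncnorm1(comps$mean[4], comps$sd[4],
                                   comps$lo[4], comps$hi[4]))
        pending_afternoon <- FALSE
      }
      for (h in sort(hrs)) {
        t0 <- day0 + round(h * 3600)
        if (t0 < avail + 120) next          # still outside / too soon
        k <- sample.int(4L, 1L, prob = mix)
        dur_s <- .draw_duration_s(k, config$p_drift)
        if (k >= 3L && stats::runif(1) < config$p_permanent_departure) {
          dep_t <- c(dep_t, t0); arr_t <- c(arr_t, NA_real_)
          cls <- c(cls, k)
          alive <- FALSE
          break
        }
        # a flight departing near the window end may return after it; the
        # truth log keeps the arrival so event alternation stays intact
        dep_t <- c(dep_t, t0); arr_t <- c(arr_t, t0 + dur_s)
        cls <- c(cls, k)
        avail <- t0 + dur_s
      }
      # resume on the day the drone actually returned (multi-day flights)
      if (is.finite(avail)) {
        w0 <- as.numeric(as.POSIXct(paste0(format(days[1]), " 00:00:00"),
                                    tz = .TZ))
        back_day <- 1L + as.integer(floor((avail - w0) / 86400))
        i_day <- max(i_day + 1L, back_day)
      } else {
        i_day <- i_day + 1L
      }
    }
    # safety net: every flyer yields at least one flight
    if (length(dep_t) == 0L) {
      day <- flight_days[ceiling(stats::runif(1) * length(flight_days))]
      day0 <- as.numeric(as.POSIXct(paste0(format(day), " 00:00:00"),
                                    tz = .TZ))
      h <- if (m_act && !a_act) .draw_hour(comps[1:3, ], w_all[1:3])
           else .rtruncnorm1(comps$mean[4], comps$sd[4], comps$lo[4],
                             comps$hi[4])
      t0 <- day0 + round(h * 3600)
      k <- sample.int(4L, 1L, prob = mix)
      dur_s <- .draw_duration_s(k, config$p_drift)
      dep_t <- t0; arr_t <- t0 + dur_s; cls <- k
    }
    nf <- length(dep_t)
    ord <- order(dep_t)
    dep_t <- dep_t[ord]; arr_t <- arr_t[ord]; cls <- cls[ord]
    lab <- .duration_class_levels[cls]
    keep_arr <- !is.na(arr_t)
    t_tag <- c(t_tag, rep(tags[d], nf + sum(keep_arr)))
    t_kind <- c(t_kind, rep(c("departure", "arrival"),
                            c(nf, sum(keep_arr))))
    t_time <- c(t_time, dep_t, arr_t[keep_arr])
    t_class <- c(t_class, lab, lab[keep_arr])
  }

  truth <- data.frame(tag_id = t_tag, kind = t_kind,
                      true_time = as.POSIXct(t_time, origin = "1970-01-01",
                                             tz = .TZ),
                      behavior_class = t_class, stringsAsFactors = FALSE)
  truth <- truth[order(truth$tag_id, truth$true_time), , drop = FALSE]
  rownames(truth) <- NULL

  # --- emit sensor reads -------------------------------------------------
  n_ev <- nrow(truth)
  if (n_ev > 0L) {
    g1 <- sample(1:2, n_ev, replace = TRUE)
    g2 <- sample(1:2, n_ev, replace = TRUE)
    is_dep <- truth$kind == "departure"
    ev_t <- as.numeric(truth$true_time)
    r_tag <- rep(truth$tag_id, each = 3L)
    r_time <- as.vector(rbind(ev_t - g1, ev_t, ev_t + g2))
    r_sensor <- as.vector(rbind(ifelse(is_dep, "A", "B"),
                                ifelse(is_dep, "B", "A"),
                                ifelse(is_dep, "B", "A")))
    keep <- stats::runif(length(r_time)) < config$p_read
    r_tag <- r_tag[keep]; r_time <- r_time[keep]; r_sensor <- r_sensor[keep]
  } else {
    r_tag <- character(0); r_time <- numeric(0); r_sensor <- character(0)
  }

  # single-read drones: one stray read, then silence
  singles <- which(fate == "single_read")
  for (d in singles) {
    day <- flight_days[ceiling(stats::runif(1) * length(flight_days))]
    day0 <- as.numeric(as.POSIXct(paste0(format(day), " 00:00:00"), tz = .TZ))
    h <- .rtruncnorm1(config$afternoon_peak_hour, 2, 6, 20)
    r_tag <- c(r_tag, tags[d])
    r_time <- c(r_time, day0 + round(h * 3600))
    r_sensor <- c(r_sensor, sample(c("A", "B"), 1L))
  }

  # spurious duplicates of real reads at a 1 s offset
  n_real <- length(r_time)
  if (n_real > 0L && config$p_spurious > 0) {
    n_sp <- stats::rpois(1, config$p_spurious * n_real)
    if (n_sp > 0L) {
      idx <- sample.int(n_real, n_sp, replace = TRUE)
      r_tag <- c(r_tag, r_tag[idx])
      r_time <- c(r_time, r_time[idx] + sample(c(-1, 1), n_sp, replace = TRUE))
      r_sensor <- c(r_sensor, r_sensor[idx])
    }
  }

  reads <- data.frame(tag_id = r_tag,
                      timestamp = as.POSIXct(r_time, origin = "1970-01-01",
                                             tz = .TZ),
                      sensor = r_sensor, stringsAsFactors = FALSE)
  reads <- reads[order(reads$tag_id, reads$timestamp), , drop = FALSE]
  rownames(reads) <- NULL

  cohort <- data.frame(tag_id = tags, fate = fate,
                       morning_active = morning_active,
                       afternoon_active = afternoon_active,
                       stringsAsFactors = FALSE)
  list(reads = reads, truth = truth, cohort = cohort)
}

#' Simulate a daily weather table
#'
#' One row per day of the observation window with mean temperature (deg C) and
#' precipitation (mm/day).  Days listed in \code{zero_activity_dates} are made
#' extreme -- the first half of them hot (>= 38 deg C) and the rest rainy
#' (>= 14 mm) -- mirroring the two heat-shutdown days and two rain-shutdown
#' days of the monitored season; all other days stay in the normal spring
#' range.
#'
#' @param config a \code{\link{sim_config}} object.
#' @return data.frame with columns \code{date}, \code{mean_temp},
#'   \code{precipitation}.
#' @export
simulate_weather <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 777L)
  days <- seq(config$start_date, config$end_date, by = "day")
  n <- length(days)
  temp <- pmin(pmax(stats::rnorm(n, 28, 3.5), 16), 36)
  wet <- stats::runif(n) < 0.3
  precip <- ifelse(wet, pmin(stats::rexp(n, 1 / 3.5), 12), 0)
  zd <- which(days %in% config$zero_activity_dates)
  if (length(zd) > 0L) {
    hot <- zd[seq_len(ceiling(length(zd) / 2))]
    rainy <- setdiff(zd, hot)
    temp[hot] <- stats::runif(length(hot), 39, 42)
    precip[hot] <- 0
    temp[rainy] <- stats::runif(length(rainy), 22, 28)
    precip[rainy] <- stats::runif(length(rainy), 14, 28)
  }
  data.frame(date = days, mean_temp = round(temp, 1),
             precipitation = round(precip, 1), stringsAsFactors = FALSE)
}
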
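test_that("summarize_drones counts flights and periods per tag", {
  # three completed flights, one final censored departure
  ev <- mk_events(rep(c("departure", "arrival"), 4)[1:7],
                  c(9, 9.05, 14, 14.1, 15, 15.1, 16) * 3600)
  sp <- classify_spans(build_spans(ev, T0, T0 + 86400))
  summ <- summarize_drones(sp)
  expect_identical(summ$n_flights_completed, 3L)
  expect_identical(summ$n_censored_departures, 1L)
  expect_identical(summ$morning_departures, 1L)
  expect_identical(summ$afternoon_departures, 3L)
  expect_true(summ$active_both_periods)
  expect_identical(summ$morning_departures + summ$afternoon_departures, 4L)
  expect_identical(summ$n_exit_entry, 1L)   # the 3 min span, edge inclusive
  expect_identical(summ$n_short_mission, 2L)
})

test_that("per-drone summaries are permutation-invariant", {
  sim <- simulate_traffic(small_config(51))
  det <- detect_events(sim$reads)
  sp <- classify_spans(build_spans(det$events))
  a <- summarize_drones(sp, sim$reads)
  perm <- sp[rev(seq_len(nrow(sp))), ]
  b <- summarize_drones(perm, sim$reads)
  expect_equal(a, b)
})

test_that("cohort_report reproduces the printed cohort arithmetic", {
  # 200 tagged, 16 never read, 20 single-read
  reads <- data.frame(
    tag_id = c(rep(sprintf("S%03d", 1:20), 1),
               rep(sprintf("M%03d", 1:164), each = 3)),
    timestamp = T0 + 1:(20 + 164 * 3),
    sensor = "A", stringsAsFactors = FALSE)
  cr <- cohort_report(reads, 200)
  expect_identical(cr$n_never_detected, 16L)
  expect_equal(cr$pct_never_detected, 8)
  expect_identical(cr$n_single_read, 20L)
  expect_equal(cr$pct_single_read, 10)
  expect_error(cohort_report(reads, 0), "cohort")
  expect_error(cohort_report(reads, 100), "more distinct tags")
})

test_that("period_fractions uses the tagged cohort as denominator", {
  mk_sum <- function(morning, afternoon) {
    data.frame(tag_id = sprintf("D%02d", seq_along(morning)),
               morning_departures = morning,
               afternoon_departures = afternoon,
               active_both_periods = morning > 0 & afternoon > 0)
  }
  pf0 <- period_fractions(mk_sum(c(0, 0), c(3, 2)), 10)
  expect_identical(pf0$morning_fraction, 0)
  expect_identical(pf0$both_fraction, 0)
  pf1 <- period_fractions(mk_sum(c(1, 1), c(1, 1)), 2)
  expect_identical(pf1$morning_fraction, 1)
  expect_identical(pf1$both_fraction, 1)
  pf <- period_fractions(mk_sum(c(2, 0, 1, 0), c(0, 1, 4, 2)), 8)
  expect_equal(pf$morning_fraction, 2 / 8)
  expect_equal(pf$both_fraction, 1 / 8)
  expect_true(pf$both_fraction <= pf$morning_fraction)
  expect_error(period_fractions(mk_sum(1, 1), 0), "cohort")
})

test_that("hourly_profile bins flights by departure hour and duration", {
  ev <- mk_events(c("departure", "arrival"),
                  c(15 * 3600 + 300, 15 * 3600 + 720))  # 15:05 + 7 min
  prof <- hourly_profile(classify_spans(build_spans(ev)))
  expect_identical(nrow(prof), 96L)
  expect_identical(prof$n[prof$hour == 15 &
                            prof$duration_class == "3_to_10min"], 1L)
  expect_identical(sum(prof$n), 1L)
  # grand total equals completed flights on simulated data
  sim <- simulate_traffic(small_config(52))
  sp <- classify_spans(build_spans(detect_events(sim$reads)$events))
  prof2 <- hourly_profile(sp)
  expect_identical(sum(prof2$n),
                   sum(sp$location == "outside" & sp$censored == "none"))
})

test_that("departure_groups assigns clock-time windows", {
  ev <- mk_events(rep("departure", 3), c(3 + 10 / 60, 9, 17) * 3600)
  got <- departure_groups(ev)
  expect_identical(got$group, c("dawn", "ungrouped", "late_afternoon"))
  # arrivals are not grouped
  ev2 <- mk_events(c("departure", "arrival"), c(3, 3.1) * 3600)
  expect_identical(departure_groups(ev2)$group, c("dawn", NA_character_))
  expect_error(departure_groups(ev, windows = list(a = c(2, 6),
                                                   b = c(5, 8))),
               "overlap")
})

test_that("unusual_activity flags long morning flights with afternoon returns", {
  mk_flight <- function(dep_h, arr_h) {
    build_spans(mk_events(c("departure", "arrival"),
                          c(dep_h, arr_h) * 3600))
  }
  flagged <- unusual_activity(classify_spans(mk_flight(6.5, 15)))
  expect_identical(nrow(flagged), 1L)
  # <= 60 min: not flagged
  expect_identical(nrow(unusual_activity(classify_spans(mk_flight(6.5, 7)))),
                   0L)
  # afternoon departure: not flagged
  expect_identical(nrow(unusual_activity(classify_spans(mk_flight(13, 15)))),
                   0L)
  # returns after 18:00: not flagged
  expect_identical(nrow(unusual_activity(classify_spans(mk_flight(6, 19)))),
                   0L)
})

test_that("daily_series zero-fills the window and averages durations", {
  ev <- mk_events(rep(c("departure", "arrival"), 2),
                  86400 + c(10, 10 + 4 / 60, 12, 12 + 6 / 60) * 3600)
  sp <- classify_spans(build_spans(ev))
  ds <- daily_series(sp, as.Date(T0), as.Date(T0) + 2)
  expect_identical(ds$n_flights, c(0L, 2L, 0L))
  expect_identical(ds$n_active_drones, c(0L, 1L, 0L))
  expect_equal(ds$mean_flight_duration, c(NA, 5, NA))
  # simulator shutdown days have exactly zero flights
  cfg <- small_config(53)
  sim <- simulate_traffic(cfg)
  sp2 <- classify_spans(build_spans(detect_events(sim$reads)$events))
  ds2 <- daily_series(sp2, cfg$start_date, cfg$end_date)
  expect_true(all(ds2$n_flights[ds2$date %in% cfg$zero_activity_dates] == 0))
  expect_identical(sum(ds2$n_flights), sum(hourly_profile(sp2)$n))
})
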
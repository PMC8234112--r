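test_that("build_spans pairs complementary events into spans", {
  # departure 14:00, arrival 14:07 -> 7 min outside
  ev <- mk_events(c("departure", "arrival"), c(14, 14 + 7 / 60) * 3600)
  sp <- build_spans(ev)
  expect_identical(sp$location, "outside")
  expect_identical(sp$censored, "none")
  expect_equal(sp$duration_min, 7)
  # arrival 14:07, departure 15:00 -> 53 min inside
  ev2 <- mk_events(c("arrival", "departure"), c(14 + 7 / 60, 15) * 3600)
  sp2 <- build_spans(ev2, T0, T0 + 86400)
  expect_identical(sp2$location, c("outside", "inside", "outside"))
  expect_identical(sp2$censored, c("left", "none", "right"))
  # the middle pair arrival->departure is the only resolved span
  sp2b <- build_spans(ev2)[2, ]
  expect_identical(sp2b$location, "inside")
  expect_equal(sp2b$duration_min, 53)
})

test_that("censoring markers follow the event stream's edges", {
  # a single departure with nothing after it: right-censored outside span
  sp <- build_spans(mk_events("departure", 14 * 3600), T0, T0 + 86400)
  expect_identical(sp$location, "outside")
  expect_identical(sp$censored, "right")
  expect_true(is.na(sp$duration_min))
  # a leading arrival: left-censored outside span
  sp2 <- build_spans(mk_events(c("arrival", "departure", "arrival"),
                               c(8, 14, 14.1) * 3600))
  expect_identical(sp2$censored, c("left", "none", "none"))
  expect_identical(sp2$location, c("outside", "inside", "outside"))
  # same-kind neighbours: broken span, excluded from duration stats
  sp3 <- build_spans(mk_events(c("departure", "departure", "arrival"),
                               c(8, 14, 14.1) * 3600))
  expect_identical(sp3$censored, c("broken", "none"))
  expect_true(is.na(sp3$duration_min[1]))
})

test_that("out-of-order events are a hard error", {
  ev <- mk_events(c("departure", "arrival"), c(15, 14) * 3600)
  expect_error(build_spans(ev), "chronological")
})

test_that("classify_spans implements the duration partition", {
  cases <- list(
    list(2, "exit_entry"),          # defecation / bearding sortie
    list(7, "short_mission"),       # orientation flight
    list(45, "scouting"),           # DCA search
    list(3, "exit_entry"),          # upper edge inclusive
    list(26 * 60, "extended_absence"))
  for (cs in cases) {
    got <- classify_spans(mk_span(cs[[1]]))
    expect_identical(as.character(got$category), cs[[2]])
  }
  expect_identical(classify_spans(mk_span(26 * 60))$days_away, 2L)
  # inside spans
  expect_identical(
    as.character(classify_spans(mk_span(31, location = "inside"))$category),
    "resting")
  expect_identical(
    as.character(classify_spans(mk_span(12, location = "inside"))$category),
    "brief_inside")
  # resting beyond the 10 h table bound keeps the category, flagged
  long <- classify_spans(mk_span(11 * 60, location = "inside"))
  expect_identical(as.character(long$category), "resting")
  expect_true(long$long_stay)
  # censored spans
  expect_identical(
    as.character(classify_spans(mk_span(NA, censored = "right"))$category),
    "departed_drone")
  expect_identical(
    as.character(classify_spans(mk_span(NA, censored = "broken"))$category),
    "unresolved")
  expect_identical(
    as.character(classify_spans(mk_span(NA, censored = "left"))$category),
    "unresolved")
  expect_error(classify_spans(mk_span(-5)), "negative")
})

test_that("every span gets exactly one category, idempotently", {
  set.seed(77)
  durs <- c(runif(200, 1 / 120, 2000), 1 / 60, 3, 10, 600)
  sp <- do.call(rbind, lapply(durs, function(d)
    mk_span(d, location = sample(c("outside", "inside"), 1))))
  got <- classify_spans(sp)
  expect_false(any(is.na(got$category)))
  expect_identical(classify_spans(got[, names(sp)])$category, got$category)
  # outside categories agree with the independently derived rule
  outs <- got[got$location == "outside", ]
  expect_identical(as.character(outs$category),
                   vapply(outs$duration_min, oracle_outside_category,
                          character(1)))
})

test_that("noiseless simulation recovers the ground-truth categories", {
  sim <- simulate_traffic(small_config(41, p_read = 1, p_spurious = 0))
  det <- detect_events(sim$reads)
  sp <- classify_spans(build_spans(det$events))
  fl <- sp[sp$location == "outside" & sp$censored == "none", ]
  # expected categories from the truth durations, derived independently
  expected <- unlist(lapply(split(sim$truth, sim$truth$tag_id), function(x) {
    k <- x$kind; t <- as.numeric(x$true_time)
    i <- which(k[-nrow(x)] == "departure" & k[-1] == "arrival")
    vapply((t[i + 1] - t[i]) / 60, oracle_outside_category, character(1))
  }))
  expect_identical(sort(as.character(fl$category)),
                   sort(unname(expected)))
})
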
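test_that("the grammar triples map to events at the middle read", {
  # departure (A,B,B) timestamped at its middle read
  dep <- detect_events(mk_reads(c("A", "B", "B")))$events
  expect_identical(dep$kind, "departure")
  expect_identical(dep$timestamp, T0 + 2)
  # arrival (B,A,A)
  arr <- detect_events(mk_reads(c("B", "A", "A")))$events
  expect_identical(arr$kind, "arrival")
  expect_identical(arr$timestamp, T0 + 2)
  # the full departure & arrival series A,B,B,A,A: the shared boundary read
  # closes the departure and opens the arrival
  both <- detect_events(mk_reads(c("A", "B", "B", "A", "A")))$events
  expect_identical(both$kind, c("departure", "arrival"))
  expect_identical(both$timestamp, T0 + c(2, 4))
  # per-event triples concatenated (A,B,B | B,A,A) parse identically
  six <- detect_events(mk_reads(c("A", "B", "B", "B", "A", "A")))$events
  expect_identical(six$kind, c("departure", "arrival"))
  expect_identical(six$timestamp, T0 + c(2, 5))
})

test_that("empty input yields no events and an empty report", {
  res <- detect_events(mk_reads(character(0), numeric(0)))
  expect_identical(nrow(res$events), 0L)
  expect_identical(res$report$n_reads_total, 0L)
  expect_identical(res$report$n_reads_unmatched, 0L)
})

test_that("strict matching equals the leftmost-suffix oracle on random noise", {
  set.seed(404)
  for (rep in 1:100) {
    len <- sample(5:40, 1)
    sensors <- sample(c("A", "B"), len, replace = TRUE)
    got <- detect_events(mk_reads(sensors))$events
    exp <- oracle_detect(sensors)
    expect_identical(got$kind, exp$kind)
    expect_identical(as.numeric(got$timestamp - T0), as.numeric(exp$mid))
  }
})

test_that("matched triples are same-tag, time-ordered, and tallied", {
  set.seed(405)
  sensors <- sample(c("A", "B"), 60, replace = TRUE)
  reads <- rbind(mk_reads(sensors, tag = "D0002"),
                 mk_reads(c("A", "B", "B"), tag = "D0001"))
  reads <- reads[order(reads$tag_id, reads$timestamp), ]
  res <- detect_events(reads)
  ev <- res$events
  for (i in seq_len(nrow(ev))) {
    idx <- c(ev$i1[i], ev$i2[i], ev$i3[i])
    expect_identical(unique(reads$tag_id[idx]), ev$tag_id[i])
    expect_true(!is.unsorted(reads$timestamp[idx]))
  }
  expect_identical(res$report$n_reads_consumed +
                     res$report$n_reads_unmatched,
                   res$report$n_reads_total)
})

test_that("tag order in the input never changes a tag's event list", {
  sim <- simulate_traffic(small_config(31))
  fwd <- detect_events(sim$reads)$events
  # reorder tags by descending name, keeping per-tag time order
  rev_reads <- sim$reads[order(factor(sim$reads$tag_id,
                                      levels = rev(sort(unique(
                                        sim$reads$tag_id)))),
                               sim$reads$timestamp), ]
  bwd <- detect_events(rev_reads)$events
  for (tg in unique(fwd$tag_id)) {
    a <- fwd[fwd$tag_id == tg, c("kind", "timestamp")]
    b <- bwd[bwd$tag_id == tg, c("kind", "timestamp")]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("unsorted or unlabelled input is a hard error", {
  bad <- mk_reads(c("A", "B", "B"), times = c(3, 2, 1))
  expect_error(detect_events(bad), "not time-sorted")
  bad2 <- mk_reads(c("A", "X", "B"))
  expect_error(detect_events(bad2), "sensor")
  expect_error(detect_events(mk_reads("A"), debounce_s = -1), "debounce")
})

test_that("same-kind consecutive events are kept and counted", {
  # two departures with the arrival lost between them
  reads <- rbind(flight_reads(9, 5)[1:3, ], flight_reads(15, 5))
  res <- detect_events(reads)
  expect_identical(res$events$kind, c("departure", "departure", "arrival"))
  expect_identical(res$report$n_inconsistent_transitions, 1L)
})

test_that("debounce collapses read bursts but leaves the grammar intact", {
  # chattering sensor: A repeated within 1 s, then the true triple
  reads <- mk_reads(c("A", "A", "B", "B"), times = c(1, 1.6, 5, 9))
  res0 <- detect_events(reads)              # default: off
  expect_identical(res0$report$n_debounced, 0L)
  res <- detect_events(reads, debounce_s = 1)
  expect_identical(res$report$n_debounced, 1L)
  expect_identical(res$events$kind, "departure")
  # the double-B signature (4 s apart) must survive a small debounce
  expect_identical(res$events$timestamp, T0 + 5)
})

test_that("lenient mode only ever adds inferred departures", {
  sim <- simulate_traffic(small_config(33, p_read = 0.9))
  strict <- detect_events(sim$reads, mode = "strict")
  lenient <- detect_events(sim$reads, mode = "lenient")
  expect_gte(nrow(lenient$events), nrow(strict$events))
  added <- lenient$events[lenient$events$inferred, ]
  expect_true(all(added$kind == "departure"))
  expect_equal(lenient$events[!lenient$events$inferred,
                              c("kind", "timestamp")],
               strict$events[, c("kind", "timestamp")],
               ignore_attr = TRUE)
})

test_that("is_morning splits the day strictly before noon", {
  ts <- as.POSIXct(c("2017-10-20 11:59:59", "2017-10-20 12:00:00",
                     "2017-10-20 03:00:00", "2017-10-20 00:00:00"),
                   tz = "UTC")
  expect_identical(is_morning(ts), c(TRUE, FALSE, TRUE, TRUE))
  ev <- mk_events("departure", 3 * 3600)
  expect_true(is_morning(ev))
})
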
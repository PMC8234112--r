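# shared fixture builders; everything is generated in code, no data files

T0 <- as.POSIXct("2017-10-20 00:00:00", tz = "UTC")

mk_reads <- function(sensors, times = seq_along(sensors), tag = "D0001") {
  data.frame(tag_id = rep_len(tag, length(sensors)), timestamp = T0 + times,
             sensor = sensors, stringsAsFactors = FALSE)
}

mk_events <- function(kinds, times, tag = "D0001") {
  data.frame(tag_id = tag, kind = kinds, timestamp = T0 + times,
             inferred = FALSE, stringsAsFactors = FALSE)
}

# a bare span row for classification tests (duration in minutes)
mk_span <- function(duration_min, location = "outside", censored = "none",
                    start = T0, tag = "D0001") {
  data.frame(tag_id = tag, location = location, start = start,
             end = start + duration_min * 60, duration_min = duration_min,
             censored = censored, stringsAsFactors = FALSE)
}

# read stream for one completed flight: departure triple then arrival triple
flight_reads <- function(dep, dur_min, tag = "D0001") {
  dep <- T0 + dep * 3600
  arr <- dep + round(dur_min * 60)
  data.frame(tag_id = tag,
             timestamp = c(dep - 1, dep, dep + 1, arr - 1, arr, arr + 1),
             sensor = c("A", "B", "B", "B", "A", "A"),
             stringsAsFactors = FALSE)
}

# small fast simulator config for property tests
small_config <- function(seed,
                         zero_activity_dates = c("2017-10-17", "2017-10-18"),
                         ...) {
  sim_config(n_drones = 40L, start_date = "2017-10-15",
             end_date = "2017-10-28",
             zero_activity_dates = zero_activity_dates,
             seed = seed, ...)
}
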
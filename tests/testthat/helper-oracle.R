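# independent oracles, deliberately implemented by different mechanisms than
# the package code they check

# crossing-grammar oracle: recursive leftmost regex match on the remaining
# suffix of the sensor string; a matched triple's final read stays available
oracle_detect <- function(sensors) {
  s <- paste(sensors, collapse = "")
  kind <- character(0); mid <- integer(0)
  offset <- 0L
  repeat {
    m <- regexpr("ABB|BAA", s)
    if (m == -1L) break
    i <- as.integer(m)
    kind <- c(kind, if (substr(s, i, i + 2L) == "ABB") "departure"
                    else "arrival")
    mid <- c(mid, offset + i + 1L)
    offset <- offset + i + 1L
    s <- substr(s, i + 2L, nchar(s))
  }
  data.frame(kind = kind, mid = mid, stringsAsFactors = FALSE)
}

# Mann-Whitney U oracle: O(n1*n2) enumeration of pairwise wins + half-ties
oracle_u <- function(x, y) {
  wins_x <- 0
  for (xi in x) for (yj in y)
    wins_x <- wins_x + (xi > yj) + 0.5 * (xi == yj)
  min(wins_x, length(x) * length(y) - wins_x)
}

# textbook Pearson correlation: covariance over product of sd's, n-1 form
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) / (n - 1) /
    (stats::sd(x) * stats::sd(y))
}

# expected behavior category from a completed outside duration (minutes),
# re-derived arithmetically, independent of classify_spans()
oracle_outside_category <- function(d) {
  if (d < 1 / 60) "unresolved"
  else if (d <= 3) "exit_entry"
  else if (d <= 10) "short_mission"
  else if (d <= 600) "scouting"
  else "extended_absence"
}
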
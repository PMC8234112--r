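#' Reconstruct departure and arrival events from raw reads
#'
#' Applies the dual-sensor crossing grammar per tag: a contiguous read triple
#' (A, B, B) is a completed departure and (B, A, A) a completed arrival, the
#' event time being the timestamp of the middle read.  Matching is a single
#' greedy left-to-right scan; on a non-match the scan advances one read (the
#' skipped read is tallied as unmatched, not consumed).  A matched triple's
#' final read may serve as the first read of the next triple, so the full
#' round-trip series A, B, B, A, A yields one departure and one arrival.
#'
#' In \code{"lenient"} mode, after strict matching, an unmatched (A, B) read
#' pair immediately followed by a matched arrival is additionally emitted as
#' an inferred departure timestamped at its B read (a departure whose
#' confirmation read was lost).
#'
#' @param reads data.frame of reads (\code{tag_id}, \code{timestamp},
#'   \code{sensor}), sorted by time within each tag.  Unsorted input is a
#'   hard error.
#' @param mode \code{"strict"} (default) or \code{"lenient"}.
#' @param debounce_s collapse same-tag, same-sensor reads closer than this
#'   many seconds before matching.  Default 0 (off): the grammar's double-B /
#'   double-A signature is itself a same-sensor repeat, so any nonzero value
#'   must stay well below the intra-triple read gap.
#' @return a list with
#'   \describe{
#'     \item{events}{data.frame \code{tag_id}, \code{kind}
#'       ("departure"/"arrival"), \code{timestamp}, \code{i1,i2,i3} (row
#'       indices of the matched reads in \code{reads}), \code{inferred};
#'       chronological within each tag.}
#'     \item{report}{list \code{n_reads_total}, \code{n_reads_consumed},
#'       \code{n_reads_unmatched}, \code{n_debounced},
#'       \code{n_inconsistent_transitions} (same-kind consecutive events
#'       per tag, summed), \code{n_inferred}.}
#'   }
#' @examples
#' t0 <- as.POSIXct("2017-10-20 14:00:00", tz = "UTC")
#' reads <- data.frame(tag_id = "D1", timestamp = t0 + c(0, 2, 3, 420, 422),
#'                     sensor = c("A", "B", "B", "A", "A"))
#' detect_events(reads)$events   # one departure, one arrival
#' @export
detect_events <- function(reads, mode = c("strict", "lenient"),
                          debounce_s = 0) {
  mode <- match.arg(mode)
  if (debounce_s < 0) stop("debounce_s must be >= 0", call. = FALSE)
  stopifnot(all(c("tag_id", "timestamp", "sensor") %in% names(reads)))
  if (!all(reads$sensor %in% c("A", "B")))
    stop("unknown sensor label; clean the input with read_rfid_log()",
         call. = FALSE)

  n_total <- nrow(reads)
  empty_events <- data.frame(tag_id = character(0), kind = character(0),
                             timestamp = as.POSIXct(character(0), tz = .TZ),
                             i1 = integer(0), i2 = integer(0),
                             i3 = integer(0), inferred = logical(0),
                             stringsAsFactors = FALSE)
  if (n_total == 0L)
    return(list(events = empty_events,
                report = list(n_reads_total = 0L, n_reads_consumed = 0L,
                              n_reads_unmatched = 0L, n_debounced = 0L,
                              n_inconsistent_transitions = 0L,
                              n_inferred = 0L)))

  ord_ok <- tapply(as.numeric(reads$timestamp), reads$tag_id,
                   function(t) !is.unsorted(t))
  if (!all(ord_ok))
    stop("reads are not time-sorted within tag(s): ",
         paste(names(ord_ok)[!ord_ok], collapse = ", "), call. = FALSE)

  idx_by_tag <- split(seq_len(n_total), reads$tag_id)
  ev_list <- vector("list", length(idx_by_tag))
  n_consumed <- 0L; n_debounced <- 0L; n_inconsistent <- 0L; n_inferred <- 0L

  for (k in seq_along(idx_by_tag)) {
    idx <- idx_by_tag[[k]]
    s <- reads$sensor[idx]
    tt <- as.numeric(reads$timestamp[idx])
    m <- length(idx)

    keep <- rep(TRUE, m)
    if (debounce_s > 0 && m > 1L) {
      last_kept <- 1L
      for (j in 2:m) {
        if (s[j] == s[last_kept] && tt[j] - tt[last_kept] <= debounce_s)
          keep[j] <- FALSE
        else last_kept <- j
      }
      n_debounced <- n_debounced + sum(!keep)
      s <- s[keep]; tt <- tt[keep]; idx <- idx[keep]
      m <- length(idx)
    }

    matched <- rep(FALSE, m)
    kinds <- character(0); mids <- integer(0)
    i1s <- integer(0); i2s <- integer(0); i3s <- integer(0)
    arr_start <- integer(0)   # local index of each matched arrival's 1st read
    i <- 1L
    while (i + 2L <= m) {
      tri <- paste0(s[i], s[i + 1L], s[i + 2L])
      if (tri == "ABB" || tri == "BAA") {
        kinds <- c(kinds, if (tri == "ABB") "departure" else "arrival")
        mids <- c(mids, i + 1L)
        i1s <- c(i1s, i); i2s <- c(i2s, i + 1L); i3s <- c(i3s, i + 2L)
        if (tri == "BAA") arr_start <- c(arr_start, i)
        matched[i:(i + 2L)] <- TRUE
        i <- i + 2L   # boundary read may start the next triple
      } else {
        i <- i + 1L
      }
    }
    inferred <- rep(FALSE, length(kinds))

    if (mode == "lenient" && length(arr_start) > 0L && m >= 2L) {
      for (j in seq_len(m - 1L)) {
        if (!matched[j] && !matched[j + 1L] &&
            s[j] == "A" && s[j + 1L] == "B" &&
            (j + 2L) %in% arr_start) {
          kinds <- c(kinds, "departure")
          mids <- c(mids, j + 1L)
          i1s <- c(i1s, j); i2s <- c(i2s, j + 1L); i3s <- c(i3s, NA_integer_)
          inferred <- c(inferred, TRUE)
          matched[j:(j + 1L)] <- TRUE
          n_inferred <- n_inferred + 1L
        }
      }
    }

    n_consumed <- n_consumed + sum(matched)
    if (length(kinds) > 0L) {
      ord <- order(tt[mids])
      kinds <- kinds[ord]; mids <- mids[ord]
      i1s <- i1s[ord]; i2s <- i2s[ord]; i3s <- i3s[ord]
      inferred <- inferred[ord]
      if (length(kinds) > 1L)
        n_inconsistent <- n_inconsistent +
          sum(kinds[-1] == kinds[-length(kinds)])
      ev_list[[k]] <- data.frame(
        tag_id = reads$tag_id[idx[1L]], kind = kinds,
        timestamp = as.POSIXct(tt[mids], origin = "1970-01-01", tz = .TZ),
        i1 = idx[i1s], i2 = idx[i2s],
        i3 = ifelse(is.na(i3s), NA_integer_, idx[pmax(i3s, 1L)]),
        inferred = inferred, stringsAsFactors = FALSE)
    }
  }

  events <- do.call(rbind, c(list(empty_events),
                             ev_list[!vapply(ev_list, is.null, logical(1))]))
  rownames(events) <- NULL
  report <- list(n_reads_total = n_total,
                 n_reads_consumed = n_consumed,
                 n_reads_unmatched = n_total - n_consumed - n_debounced,
                 n_debounced = n_debounced,
                 n_inconsistent_transitions = n_inconsistent,
                 n_inferred = n_inferred)
  list(events = events, report = report)
}

#' Is an event a morning event?
#'
#' Morning means a clock time strictly before 12:00 noon; 12:00:00 itself is
#' afternoon.  Accepts a POSIXct vector or an event data.frame.
#'
#' @param event event data.frame (uses its \code{timestamp} column) or a
#'   POSIXct vector.
#' @return logical vector.
#' @export
is_morning <- function(event) {
  t <- if (is.data.frame(event)) event$timestamp else event
  .clock_hour(t) < 12
}
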
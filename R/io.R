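#' RFID log dialect
#'
#' Names the three columns of a raw reader log and the timestamp format.
#' The default matches the simulator's output: comma-separated, columns
#' \code{tag_id}, \code{timestamp} (ISO 8601 local civil time, no zone
#' offset), \code{sensor} with values "A"/"B".
#'
#' @param col_tag,col_time,col_sensor column names in the file.
#' @param ts_format timestamp format string for \code{strptime}.
#' @param sep field separator.
#' @return a named list of class \code{rfid_dialect}.
#' @export
rfid_dialect <- function(col_tag = "tag_id", col_time = "timestamp",
                         col_sensor = "sensor",
                         ts_format = .TS_FORMAT, sep = ",") {
  structure(list(col_tag = col_tag, col_time = col_time,
                 col_sensor = col_sensor, ts_format = ts_format, sep = sep),
            class = "rfid_dialect")
}

#' Read a raw RFID reader log
#'
#' Parses a delimited-text log (one read per line) into the canonical read
#' table.  Lines whose timestamp does not parse, or whose sensor label is not
#' "A"/"B", are rejected and tallied -- never silently dropped: the returned
#' data.frame carries a \code{reject_report} attribute with the rejected line
#' numbers.  A missing column is a hard error naming the column.
#'
#' @param path file path.
#' @param dialect an \code{\link{rfid_dialect}}.
#' @return data.frame with columns \code{tag_id}, \code{timestamp} (POSIXct),
#'   \code{sensor}, sorted by (tag_id, timestamp, input order), with
#'   attribute \code{reject_report} = list(n_rejected, lines).
#' @export
read_rfid_log <- function(path, dialect = rfid_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", stringsAsFactors = FALSE,
                           check.names = FALSE)
  for (col in c(dialect$col_tag, dialect$col_time, dialect$col_sensor)) {
    if (!col %in% names(raw))
      stop("required column missing from ", path, ": '", col, "'",
           call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) {
    out <- data.frame(tag_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = .TZ),
                      sensor = character(0), stringsAsFactors = FALSE)
    attr(out, "reject_report") <- list(n_rejected = 0L, lines = integer(0))
    return(out)
  }
  ts <- as.POSIXct(strptime(raw[[dialect$col_time]], dialect$ts_format,
                            tz = .TZ))
  sensor <- raw[[dialect$col_sensor]]
  bad <- is.na(ts) | !(sensor %in% c("A", "B"))
  if (any(bad))
    message(sum(bad), " malformed line(s) rejected from ", path)
  out <- data.frame(tag_id = raw[[dialect$col_tag]][!bad],
                    timestamp = ts[!bad], sensor = sensor[!bad],
                    stringsAsFactors = FALSE)
  out <- out[order(out$tag_id, out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reject_report") <- list(n_rejected = sum(bad),
                                     lines = which(bad))
  out
}

# internal: write a data.frame as CSV with ISO timestamps, no row names
.write_csv <- function(df, path, time_cols = character(0)) {
  for (col in time_cols)
    if (col %in% names(df)) df[[col]] <- .fmt_time(df[[col]])
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}

.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read pipeline record tables
#'
#' CSV serialisation for the pipeline's record types.  Timestamps are written
#' as ISO 8601 local civil time with 1 s resolution and no zone offset; all
#' writers round-trip losslessly through their paired reader.  An empty table
#' produces a header-only file.
#'
#' @param reads,events,spans,summaries data.frames as produced by the
#'   pipeline stages.
#' @param path file path to write to / read from.
#' @return the path (writers, invisibly) or the parsed data.frame (readers).
#' @name rfid_io
NULL

#' @rdname rfid_io
#' @export
write_reads <- function(reads, path) {
  .write_csv(reads[, c("tag_id", "timestamp", "sensor")], path, "timestamp")
}

#' @rdname rfid_io
#' @export
write_events <- function(events, path) {
  cols <- intersect(c("tag_id", "kind", "timestamp", "i1", "i2", "i3",
                      "inferred"), names(events))
  .write_csv(events[, cols, drop = FALSE], path, "timestamp")
}

#' @rdname rfid_io
#' @export
read_events <- function(path) {
  df <- .read_csv(path)
  df$timestamp <- .as_time(df$timestamp)
  if ("inferred" %in% names(df)) df$inferred <- as.logical(df$inferred)
  df
}

#' @rdname rfid_io
#' @export
write_spans <- function(spans, path) {
  .write_csv(spans, path, c("start", "end"))
}

#' @rdname rfid_io
#' @export
read_spans <- function(path) {
  df <- .read_csv(path)
  for (col in c("start", "end"))
    if (col %in% names(df)) df[[col]] <- .as_time(df[[col]])
  if ("duration_min" %in% names(df))
    df$duration_min <- as.numeric(df$duration_min)
  df
}

#' @rdname rfid_io
#' @export
write_summary <- function(summaries, path) {
  .write_csv(summaries, path, c("first_seen", "last_seen"))
}

#' @rdname rfid_io
#' @export
read_summary <- function(path) {
  df <- .read_csv(path)
  for (col in c("first_seen", "last_seen"))
    if (col %in% names(df)) df[[col]] <- .as_time(df[[col]])
  if ("active_both_periods" %in% names(df))
    df$active_both_periods <- as.logical(df$active_both_periods)
  df
}

#' @rdname rfid_io
#' @param weather data.frame as from \code{\link{simulate_weather}}.
#' @export
write_weather <- function(weather, path) {
  w <- weather
  w$date <- format(w$date)
  .write_csv(w, path)
}

#' @rdname rfid_io
#' @export
read_weather <- function(path) {
  df <- .read_csv(path)
  df$date <- as.Date(df$date)
  if (any(df$precipitation < 0, na.rm = TRUE))
    stop("negative precipitation in ", path, call. = FALSE)
  if (anyDuplicated(df$date))
    stop("duplicate dates in ", path, call. = FALSE)
  df
}
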
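#' Pipeline configuration
#'
#' One nested configuration object covering every stage, with the monitored
#' season's analysis as the zero-configuration default: the simulator
#' defaults of \code{\link{sim_config}}, strict grammar matching with no
#' debounce, the duration thresholds of \code{\link{behavior_thresholds}},
#' the 12:00 morning cutoff, the four departure-time group windows, and
#' flight-count chi-square bins 1-9 / 10-29 / 30-49.
#'
#' @param seed integer seed forwarded to the simulator.
#' @param sim a \code{\link{sim_config}}.
#' @param detection list(mode, debounce_s).
#' @param classification list(thresholds = \code{behavior_thresholds()}).
#' @param summary list(group_windows, morning_cutoff).
#' @param stats list(chisq_breaks): interior upper edges of the flight-count
#'   bins; the default \code{c(9, 29)} yields the three ranges 1-9, 10-29 and
#'   30+ (df = 2).
#' @return nested list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed),
                            detection = list(mode = "strict", debounce_s = 0),
                            classification = list(
                              thresholds = behavior_thresholds()),
                            summary = list(group_windows = departure_windows(),
                                           morning_cutoff = 12),
                            stats = list(chisq_breaks = c(9, 29))) {
  cfg <- list(seed = as.integer(seed), sim = sim, detection = detection,
              classification = classification, summary = summary,
              stats = stats)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from JSON
#'
#' Reads a JSON file whose top-level keys mirror the arguments of
#' \code{\link{pipeline_config}} and \code{\link{sim_config}}; keys absent
#' from the file keep their defaults.
#'
#' @param path JSON file path.
#' @param seed optional seed overriding both the file and the default.
#' @return a \code{pipeline_config}.
#' @export
load_pipeline_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  sim_args <- raw$sim
  if (!is.null(raw$seed)) sim_args$seed <- as.integer(raw$seed)
  if (!is.null(sim_args$behavior_mix))
    sim_args$behavior_mix <- unlist(sim_args$behavior_mix)
  sim <- do.call(sim_config, if (is.null(sim_args)) list() else sim_args)
  cfg <- pipeline_config(seed = if (is.null(raw$seed)) 1L else raw$seed,
                         sim = sim)
  for (sec in c("detection", "summary", "stats"))
    for (nm in names(raw[[sec]]))
      cfg[[sec]][[nm]] <- raw[[sec]][[nm]]
  if (!is.null(raw$classification$thresholds))
    cfg$classification$thresholds <- do.call(
      behavior_thresholds, as.list(raw$classification$thresholds))
  cfg
}

# config serialised canonically for hashing and the run log
.config_json <- function(config) {
  strip <- function(x) {
    if (inherits(x, "Date")) format(x)
    else if (is.list(x)) lapply(unclass(x), strip)
    else x
  }
  jsonlite::toJSON(strip(config), auto_unbox = TRUE, digits = NA,
                   pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' simulate -> detect -> classify -> summarize -> compare, writing every
#' stage artifact to \code{out_dir}: reads/truth/weather CSVs, events, the
#' match report, classified spans, per-drone summaries, the hourly profile,
#' the daily series, cohort and period-fraction reports, the statistics, and
#' a run log recording the configuration (with its MD5 hash) and record
#' counts at each stage.  Deterministic for a fixed seed: running twice
#' produces byte-identical artifacts.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir output directory, created if needed.
#' @param reads_path optional path to an existing raw log read with
#'   \code{\link{read_rfid_log}} instead of simulating (ground truth is then
#'   unavailable and the simulate stage is skipped).
#' @param verbose emit per-stage progress via \code{message()}.
#' @return (invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "drone_run",
                         reads_path = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[droneactivity] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cfg_json <- .config_json(config)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  if (is.null(reads_path)) {
    say("simulate: ", config$sim$n_drones, " drones, seed ", config$sim$seed)
    sim <- stage("simulate", simulate_traffic(config$sim))
    weather <- stage("simulate", simulate_weather(config$sim))
    reads <- sim$reads; truth <- sim$truth; cohort <- sim$cohort
    n_tagged <- config$sim$n_drones
    write_reads(reads, file.path(out_dir, "reads.csv"))
    .write_csv(truth, file.path(out_dir, "truth.csv"), "true_time")
    write_weather(weather, file.path(out_dir, "weather.csv"))
  } else {
    say("read: ", reads_path)
    reads <- stage("read", read_rfid_log(reads_path))
    truth <- NULL; cohort <- NULL
    weather <- stage("simulate", simulate_weather(config$sim))
    n_tagged <- config$sim$n_drones
  }

  say("detect: ", nrow(reads), " reads")
  det <- stage("detect", detect_events(reads, mode = config$detection$mode,
                                       debounce_s = config$detection$debounce_s))
  write_events(det$events, file.path(out_dir, "events.csv"))
  jsonlite::write_json(det$report, file.path(out_dir, "match_report.json"),
                       auto_unbox = TRUE)

  say("classify: ", nrow(det$events), " events")
  ws <- as.POSIXct(paste0(format(config$sim$start_date), " 00:00:00"),
                   tz = .TZ)
  we <- as.POSIXct(paste0(format(config$sim$end_date), " 23:59:59"),
                   tz = .TZ)
  spans <- stage("classify", build_spans(det$events, ws, we))
  cspans <- stage("classify",
                  classify_spans(spans, config$classification$thresholds))
  write_spans(cspans, file.path(out_dir, "spans.csv"))

  say("summarize: ", nrow(cspans), " spans")
  summaries <- stage("summarize", summarize_drones(cspans, reads))
  write_summary(summaries, file.path(out_dir, "drone_summary.csv"))
  cohort_rep <- stage("summarize", cohort_report(reads, n_tagged))
  fractions <- stage("summarize", period_fractions(summaries, n_tagged))
  profile <- stage("summarize", hourly_profile(cspans))
  daily <- stage("summarize",
                 daily_series(cspans, config$sim$start_date,
                              config$sim$end_date))
  unusual <- stage("summarize", unusual_activity(cspans))
  .write_csv(profile, file.path(out_dir, "hourly_profile.csv"))
  dly <- daily; dly$date <- format(dly$date)
  .write_csv(dly, file.path(out_dir, "daily_activity.csv"))
  write_spans(unusual, file.path(out_dir, "unusual_activity.csv"))
  jsonlite::write_json(c(cohort_rep, fractions),
                       file.path(out_dir, "cohort.json"), auto_unbox = TRUE,
                       digits = NA)

  say("compare: statistics")
  stats_out <- stage("compare", {
    breaks <- unique(c(0, config$stats$chisq_breaks, Inf))
    counts <- summaries$n_flights_completed
    counts <- counts[counts > 0]
    binned <- table(cut(counts, breaks))
    chisq <- chi_square_gof(as.integer(binned),
                            rep(sum(binned) / length(binned),
                                length(binned)))
    wc <- weather_correlation(daily, weather)
    morning_daily <- vapply(split(
      is_morning(cspans$start[cspans$location == "outside" &
                                cspans$censored == "none"]),
      as.Date(cspans$start[cspans$location == "outside" &
                             cspans$censored == "none"], tz = .TZ)),
      sum, numeric(1))
    afternoon_daily <- vapply(split(
      !is_morning(cspans$start[cspans$location == "outside" &
                                 cspans$censored == "none"]),
      as.Date(cspans$start[cspans$location == "outside" &
                             cspans$censored == "none"], tz = .TZ)),
      sum, numeric(1))
    mww <- mann_whitney_u(morning_daily, afternoon_daily)
    list(flight_count_chisq = unclass(chisq),
         morning_vs_afternoon_mww = unclass(mww),
         weather = lapply(wc, unclass))
  })
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)

  run_log <- list(config_md5 = cfg_hash,
                  seed = config$seed,
                  counts = list(reads = nrow(reads),
                                events = nrow(det$events),
                                spans = nrow(cspans),
                                drones_summarised = nrow(summaries),
                                flights = sum(summaries$n_flights_completed),
                                unusual_flights = nrow(unusual)))
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  say("done: ", out_dir)
  invisible(list(reads = reads, truth = truth, cohort = cohort,
                 weather = weather, events = det$events,
                 match_report = det$report, spans = cspans,
                 summaries = summaries, cohort_report = cohort_rep,
                 fractions = fractions, profile = profile, daily = daily,
                 unusual = unusual, stats = stats_out))
}
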
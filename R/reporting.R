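#' @include AllClasses.R AllGenerics.R detection.R cohort.R simulate.R
NULL

.pkgVersion <- function()
  as.character(utils::packageVersion("TrackContacts"))

.configList <- function(config) list(
  distance_threshold_um = config@distanceThresholdUm,
  speed_fraction = config@speedFraction,
  cr_tolerance = config@crTolerance,
  long_threshold_s = config@longThresholdS,
  touch_and_go_s = config@touchAndGoS,
  tolerance_enabled = config@toleranceEnabled)

#' Read a detector configuration from YAML
#'
#' Reads detector thresholds from a YAML file; absent fields keep the
#' [DetectorConfig()] defaults, so a config file only has to state what it
#' overrides.
#'
#' @param path YAML file with any of the keys `distance_threshold_um`,
#'   `speed_fraction`, `cr_tolerance`, `long_threshold_s`,
#'   `touch_and_go_s`, `tolerance_enabled`.
#' @return A validated [DetectorConfig-class].
#' @export
readDetectorConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- c("distance_threshold_um", "speed_fraction", "cr_tolerance",
             "long_threshold_s", "touch_and_go_s", "tolerance_enabled")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown detector config field(s): ", paste(bad, collapse = ", "))
  d <- DetectorConfig()
  DetectorConfig(
    distanceThresholdUm = y$distance_threshold_um %||% d@distanceThresholdUm,
    speedFraction = y$speed_fraction %||% d@speedFraction,
    crTolerance = y$cr_tolerance %||% d@crTolerance,
    longThresholdS = y$long_threshold_s %||% d@longThresholdS,
    touchAndGoS = y$touch_and_go_s %||% d@touchAndGoS,
    toleranceEnabled = y$tolerance_enabled %||% d@toleranceEnabled)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a simulation configuration from YAML
#'
#' @param path YAML file; fields mirror the [SimulationConfig()] arguments
#'   in snake_case (`seed`, `n_frames`, `frame_interval_s`, `volume_um`,
#'   `n_nk`, `n_dc`, `n_t`, `nk_speed_mean_um_min`, ..., `episodes` as a
#'   list of records).
#' @return A validated [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  ep <- NULL
  if (!is.null(y$episodes) && length(y$episodes))
    ep <- do.call(rbind, lapply(y$episodes, function(e) data.frame(
      nk_id = e$nk_id, dc_id = e$dc_id,
      start_frame = as.integer(e$start_frame),
      n_frames = as.integer(e$n_frames),
      dwell_dist_um = e$dwell_dist_um %||% 12.5,
      dwell_speed_frac = e$dwell_speed_frac %||% 0.15)))
  d <- SimulationConfig()
  SimulationConfig(
    seed = y$seed %||% d@seed,
    nFrames = y$n_frames %||% d@nFrames,
    frameIntervalS = y$frame_interval_s %||% d@frameIntervalS,
    volumeUm = unlist(y$volume_um %||% d@volumeUm),
    nNk = y$n_nk %||% d@nNk, nDc = y$n_dc %||% d@nDc, nT = y$n_t %||% d@nT,
    nkSpeedMeanUmMin = y$nk_speed_mean_um_min %||% d@nkSpeedMeanUmMin,
    nkSpeedSdUmMin = y$nk_speed_sd_um_min %||% d@nkSpeedSdUmMin,
    nkSpeedWithinSdUmMin = y$nk_speed_within_sd_um_min %||%
      d@nkSpeedWithinSdUmMin,
    tSpeedMeanUmMin = y$t_speed_mean_um_min %||% d@tSpeedMeanUmMin,
    tSpeedSdUmMin = y$t_speed_sd_um_min %||% d@tSpeedSdUmMin,
    dcDriftUmMin = y$dc_drift_um_min %||% d@dcDriftUmMin,
    persistence = y$persistence %||% d@persistence,
    jitterSdUm = y$jitter_sd_um %||% d@jitterSdUm,
    dropP = y$drop_p %||% d@dropP,
    dcSeparationUm = y$dc_separation_um %||% d@dcSeparationUm,
    episodes = ep, condition = y$condition %||% d@condition)
}

.writeManifest <- function(outdir, command, configSnapshot, inputs, outputs,
                           seed = NULL) {
  manifest <- list(command = command, config = configSnapshot,
                   inputs = inputs, outputs = outputs, seed = seed,
                   tool_version = .pkgVersion(),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

.writeTsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)

#' Run the detection pipeline on a track table
#'
#' Reads a track CSV, validates every field of view (error-severity
#' findings abort with a message listing them), runs the three-criterion
#' detector over all NK-DC pairs, and writes the events table (TSV), the
#' per-condition cohort summary (JSON), optional per-pair diagnostics
#' (TSV), and a run manifest into `outdir`.
#'
#' @param tracksPath path to the track CSV (see [readTracks()]).
#' @param configPath optional YAML detector config (see
#'   [readDetectorConfig()]); NULL uses defaults.
#' @param outdir output directory (created if needed).
#' @param diagnostics write per-pair criterion diagnostics for every
#'   NK-DC pair with at least one event?
#' @return Invisibly, a list with `events`, `summary` and the output paths.
#' @export
runDetect <- function(tracksPath, configPath = NULL, outdir,
                      diagnostics = FALSE) {
  config <- if (is.null(configPath)) DetectorConfig()
            else readDetectorConfig(configPath)
  fovs <- readTracks(tracksPath)
  findings <- do.call(rbind, lapply(fovs, validateFov))
  if (!is.null(findings) && any(findings$severity == "error")) {
    bad <- findings[findings$severity == "error", , drop = FALSE]
    stop("track validation failed:\n",
         paste(sprintf("  %s (frame %s): %s", bad$cell_id, bad$frame,
                       bad$message), collapse = "\n"))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  events <- do.call(rbind, lapply(fovs, detectAll, config = config))
  if (is.null(events)) events <- .emptyEvents()
  summary <- cohortSummary(fovs, events, config)
  eventsPath <- file.path(outdir, "events.tsv")
  .writeTsv(events, eventsPath)
  summaryPath <- file.path(outdir, "cohort_summary.json")
  jsonlite::write_json(
    list(detector = .configList(config),
         speed_average_cell_types = "NK",
         t_test_variant = "unpaired, equal variance, two-tailed",
         conditions = summary),
    summaryPath, auto_unbox = TRUE, pretty = TRUE, digits = NA,
    dataframe = "rows")
  outputs <- c(eventsPath, summaryPath)
  if (diagnostics) {
    diagPath <- file.path(outdir, "diagnostics.tsv")
    diags <- list()
    for (fov in fovs) {
      ev <- events[events$fov_id == fov@fovId, , drop = FALSE]
      pairs <- unique(ev[, c("nk_id", "dc_id")])
      if (!nrow(pairs)) next
      vs <- fovAverageSpeed(fov)
      for (i in seq_len(nrow(pairs))) {
        dg <- pairDiagnostics(fov@trajectories[[pairs$nk_id[i]]],
                              fov@trajectories[[pairs$dc_id[i]]], vs, config)
        diags[[length(diags) + 1L]] <-
          data.frame(fov_id = fov@fovId, nk_id = pairs$nk_id[i],
                     dc_id = pairs$dc_id[i], dg)
      }
    }
    if (length(diags)) {
      .writeTsv(do.call(rbind, diags), diagPath)
      outputs <- c(outputs, diagPath)
    }
  }
  manifest <- .writeManifest(outdir, "detect", .configList(config),
                             inputs = c(tracksPath, configPath),
                             outputs = outputs)
  invisible(list(events = events, summary = summary,
                 outputs = c(outputs, manifest)))
}

#' Run the simulator and write standard outputs
#'
#' Simulates `nFov` fields of view from a YAML (or in-memory)
#' configuration and writes the standard track CSV, the ground-truth TSV
#' and a run manifest into `outdir`. Deterministic under the config seed.
#'
#' @param config a [SimulationConfig-class] or path to a YAML file for
#'   [readSimulationConfig()].
#' @param outdir output directory (created if needed).
#' @param nFov number of fields of view to simulate.
#' @return Invisibly, a list with `fovs`, `truth` and the output paths.
#' @export
runSimulate <- function(config, outdir, nFov = 1L) {
  configPath <- NULL
  if (is.character(config)) {
    configPath <- config
    config <- readSimulationConfig(config)
  }
  validObject(config)
  if (config@nNk < 1L) stop("config error: n_nk must be >= 1")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sims <- lapply(seq_len(nFov), function(i) simulateFov(config, fovIndex = i))
  fovs <- lapply(sims, `[[`, "fov")
  truth <- do.call(rbind, lapply(sims, `[[`, "truth"))
  tracksPath <- file.path(outdir, "tracks.csv")
  writeTracks(fovs, tracksPath)
  truthPath <- file.path(outdir, "ground_truth.tsv")
  .writeTsv(truth, truthPath)
  manifest <- .writeManifest(
    outdir, "simulate",
    list(seed = config@seed, n_fov = nFov, n_frames = config@nFrames,
         frame_interval_s = config@frameIntervalS,
         volume_um = config@volumeUm, n_nk = config@nNk,
         n_dc = config@nDc, n_t = config@nT,
         nk_speed_mean_um_min = config@nkSpeedMeanUmMin,
         nk_speed_sd_um_min = config@nkSpeedSdUmMin,
         jitter_sd_um = config@jitterSdUm, drop_p = config@dropP,
         n_episodes = nrow(config@episodes)),
    inputs = configPath, outputs = c(tracksPath, truthPath),
    seed = config@seed)
  invisible(list(fovs = fovs, truth = truth,
                 outputs = c(tracksPath, truthPath, manifest)))
}
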
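#' @include AllClasses.R AllGenerics.R detection.R
NULL

#' Fraction of NK cells interacting with DCs
#'
#' Percentage of tracked NK cells in a field of view that hold at least one
#' detected interaction event with any DC.
#'
#' @param events events data.frame from [detectAll()].
#' @param fov the [FieldOfView-class] the events were detected in.
#' @return numeric(1), percent in \[0, 100\].
#' @export
interactingFraction <- function(events, fov) {
  nkIds <- cellIds(fov, "NK")
  if (!length(nkIds)) stop("FOV ", fov@fovId, " has no NK tracks")
  100 * length(intersect(unique(events$nk_id), nkIds)) / length(nkIds)
}

#' Fraction of interacting cells with long interactions
#'
#' Percentage of interacting NK cells whose longest event is classed
#' `long`. The classification is per cell, not per event: a cell with many
#' short contacts and one long one counts once as long. Cells are keyed by
#' (`fov_id`, `nk_id`) so events from several fields of view can be pooled.
#'
#' @param events events data.frame from [detectAll()] (possibly
#'   concatenated over FOVs).
#' @return numeric(1) percent, with attributes `n_interacting`, `n_long`
#'   and `no_interacting` (TRUE when there are no interacting cells, in
#'   which case the value is 0).
#' @export
longFraction <- function(events) {
  if (!nrow(events))
    return(structure(0, n_interacting = 0L, n_long = 0L,
                     no_interacting = TRUE))
  key <- paste(events$fov_id, events$nk_id, sep = "\r")
  longestClass <- vapply(split(events, key), function(e)
    e$class[which.max(e$duration_s)], character(1))
  nInt <- length(longestClass)
  nLong <- sum(longestClass == "long")
  structure(100 * nLong / nInt, n_interacting = nInt, n_long = nLong,
            no_interacting = FALSE)
}

#' Summary of interaction durations
#'
#' Mean and standard error (SEM = sd/sqrt(n), n-1 denominator) of event
#' durations, plus per-class counts.
#'
#' @param events events data.frame from [detectAll()].
#' @return list with `n`, `mean_s`, `sem_s` (NA when n < 2) and
#'   `class_counts` (named integer vector); `n = 0` marks an empty summary.
#' @export
durationSummary <- function(events) {
  counts <- table(factor(events$class,
                         levels = c("touch_and_go", "intermediate", "long")))
  n <- nrow(events)
  list(n = n,
       mean_s = if (n) mean(events$duration_s) else NA_real_,
       sem_s = if (n >= 2L) stats::sd(events$duration_s) / sqrt(n) else NA_real_,
       class_counts = c(counts))
}

#' Per-cell 3D velocity distribution
#'
#' Mean 3D speeds of the given (interacting) NK cells, as used for cohort
#' velocity distributions grouped by condition.
#'
#' @param fov a [FieldOfView-class].
#' @param interactingIds character vector of NK cell ids (must exist in the
#'   FOV as NK tracks).
#' @return data.frame with columns `fov_id`, `condition`, `cell_id`,
#'   `v_mean_um_min`; zero rows for an empty id set.
#' @export
velocitySummary <- function(fov, interactingIds) {
  nkIds <- cellIds(fov, "NK")
  unknown <- setdiff(interactingIds, nkIds)
  if (length(unknown))
    stop("unknown NK cell id(s): ", paste(unknown, collapse = ", "))
  v <- vapply(interactingIds, function(id)
    meanTrackSpeed(fov@trajectories[[id]]), numeric(1))
  data.frame(fov_id = rep(fov@fovId, length(interactingIds)),
             condition = rep(fov@condition, length(interactingIds)),
             cell_id = as.character(interactingIds),
             v_mean_um_min = as.numeric(v), row.names = NULL)
}

#' Compare two condition samples
#'
#' Unpaired, equal-variance, two-tailed Student t-test between two samples
#' (e.g. interaction durations or per-cell velocities under two
#' conditions), with descriptive means and SEMs. A degenerate pooled
#' variance of zero is flagged rather than raised.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t`, `df`, `p`, `mean_a`, `sem_a`, `mean_b`, `sem_b`,
#'   `zero_variance` (logical; when TRUE, `t` and `p` are NA).
#' @examples
#' compareConditions(c(1, 2, 3), c(2, 3, 4))
#' @export
compareConditions <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values")
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  out <- list(t = NA_real_, df = length(a) + length(b) - 2L, p = NA_real_,
              mean_a = mean(a), sem_a = sem(a),
              mean_b = mean(b), sem_b = sem(b), zero_variance = FALSE)
  pooled <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (pooled == 0) {
    out$zero_variance <- TRUE
    return(out)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- tt$p.value
  out
}

#' Cohort summary per condition
#'
#' Aggregates detection results over fields of view into the
#' population-level readouts, per condition: number of tracked and
#' interacting NK cells, interacting fraction, long-interaction counts and
#' fractions (reported against both denominators: interacting cells and
#' all tracked cells), duration mean +/- SEM, and per-cell velocity mean
#' +/- SEM of interacting cells.
#'
#' @param fovs list of [FieldOfView-class] objects.
#' @param events events data.frame pooled over those FOVs (from
#'   [detectAll()] per FOV, rbind-ed); if NULL, detection is run here.
#' @param config a [DetectorConfig-class] (used when `events` is NULL).
#' @return data.frame with one row per condition.
#' @export
cohortSummary <- function(fovs, events = NULL, config = DetectorConfig()) {
  if (is(fovs, "FieldOfView")) fovs <- list(fovs)
  if (is.null(events))
    events <- do.call(rbind, lapply(fovs, detectAll, config = config))
  conds <- unique(vapply(fovs, function(f) f@condition, character(1)))
  rows <- lapply(conds, function(cond) {
    fs <- Filter(function(f) f@condition == cond, fovs)
    ev <- events[events$condition == cond, , drop = FALSE]
    nTracked <- sum(vapply(fs, function(f) length(cellIds(f, "NK")),
                           integer(1)))
    interKeys <- unique(paste(ev$fov_id, ev$nk_id, sep = "\r"))
    lf <- longFraction(ev)
    ds <- durationSummary(ev)
    vel <- do.call(rbind, lapply(fs, function(f)
      velocitySummary(f, intersect(unique(ev$nk_id[ev$fov_id == f@fovId]),
                                   cellIds(f, "NK")))))
    v <- if (is.null(vel)) numeric() else vel$v_mean_um_min
    data.frame(
      condition = cond,
      n_nk_tracked = nTracked,
      n_nk_interacting = length(interKeys),
      interacting_pct = 100 * length(interKeys) / max(nTracked, 1L),
      n_long = attr(lf, "n_long"),
      long_pct_of_interacting = as.numeric(lf),
      long_pct_of_tracked = 100 * attr(lf, "n_long") / max(nTracked, 1L),
      n_events = ds$n,
      duration_mean_s = ds$mean_s,
      duration_sem_s = ds$sem_s,
      velocity_mean_um_min = if (length(v)) mean(v) else NA_real_,
      velocity_sem_um_min = if (length(v) >= 2L)
        stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
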
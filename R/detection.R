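#' @include AllClasses.R AllGenerics.R motility.R
NULL

.emptyEvents <- function() {
  data.frame(fov_id = character(), condition = character(),
             nk_id = character(), dc_id = character(),
             start_frame = integer(), end_frame = integer(),
             n_frames = integer(), n_tolerated_frames = integer(),
             duration_s = numeric(), class = character())
}

#' NK-DC distance series
#'
#' Euclidean 3D centroid distance on each frame shared by the two tracks,
#' with the digitized distance criterion: met iff Dist(t_i) <= d
#' (inclusive). `dist_d` carries the plot constants -0.15 (met) / 0 (not
#' met) used to draw criterion timelines; detection uses the boolean only.
#' Frames present in only one track are absent from the series; a pair with
#' no shared frame yields a zero-row series (not an error).
#'
#' @param nk,dc [Trajectory-class] objects.
#' @param d distance threshold in micrometres (default 25).
#' @return data.frame with columns `frame`, `dist_um`, `dist_met`, `dist_d`.
#' @examples
#' nk <- Trajectory("NK1", "NK", 0:1, x = 0, y = 0, z = 0)
#' dc <- Trajectory("DC1", "DC", 0:1, x = 3, y = 4, z = 0)
#' pairDistance(nk, dc)$dist_um   # 5, 5
#' @export
pairDistance <- function(nk, dc, d = 25) {
  pn <- nk@points; pd <- dc@points
  common <- intersect(pn$frame, pd$frame)
  if (!length(common))
    return(data.frame(frame = integer(), dist_um = numeric(),
                      dist_met = logical(), dist_d = numeric()))
  common <- sort(common)
  a <- as.matrix(pn[match(common, pn$frame), c("x_um", "y_um", "z_um")])
  b <- as.matrix(pd[match(common, pd$frame), c("x_um", "y_um", "z_um")])
  dist <- sqrt(rowSums((a - b)^2))
  met <- dist <= d
  data.frame(frame = common, dist_um = dist, dist_met = met,
             dist_d = ifelse(met, -0.15, 0))
}

#' Confinement-ratio criterion
#'
#' Per-frame boolean: the confinement ratio is constant or decreasing from
#' the previous frame, up to a small tolerance: CR(t_i) <= CR(t_{i-1}) +
#' epsilon. The first frame of the series has no prior value and is FALSE
#' (conservative start).
#'
#' @param cr numeric vector of confinement ratios (ordered frames), or the
#'   data.frame returned by [confinementRatio()].
#' @param epsCr non-increase tolerance (default 0.01).
#' @return logical vector the length of `cr`.
#' @export
confinementCriterion <- function(cr, epsCr = 0.01) {
  if (is.data.frame(cr)) cr <- cr$cr
  n <- length(cr)
  if (n < 1L) return(logical())
  c(FALSE, if (n > 1L) cr[-1L] <= cr[-n] + epsCr)
}

#' Speed criterion
#'
#' Per-frame boolean: the instantaneous speed is at most the given fraction
#' of the field-of-view average speed (inclusive threshold, matching the
#' published "<= 60%" operating point). Identical to the zero-set of
#' [normalizedSpeed()].
#'
#' @param v numeric vector of instantaneous speeds (um/min), or the
#'   data.frame returned by [instantaneousSpeed()].
#' @param vFov numeric(1) or [FovSpeedSummary-class], FOV-average speed > 0.
#' @param alpha speed fraction in (0, 1), default 0.60.
#' @return logical vector the length of `v`.
#' @export
speedCriterion <- function(v, vFov, alpha = 0.60) {
  if (is.data.frame(v)) v <- v$v_um_min
  if (is(vFov, "FovSpeedSummary")) vFov <- vFov@vFov
  if (!is.numeric(vFov) || length(vFov) != 1L || vFov <= 0)
    stop("vFov must be a single positive speed (um/min)")
  v <= alpha * vFov
}

#' Segment qualifying runs from a criterion series
#'
#' The core run semantics of the detector, exposed on a bare criterion
#' matrix: rows are consecutive frames, columns the three per-frame
#' booleans (distance, speed, confinement). A frame qualifies when all
#' three hold; with tolerance, an interior frame at which exactly one
#' criterion fails is absorbed into the run when both its neighbours fully
#' qualify. Events are the maximal runs of qualifying frames. Two or more
#' consecutive failing frames always split.
#'
#' @param met logical matrix (n frames x 3 criteria) over consecutive
#'   frames.
#' @param tolerance absorb isolated single-criterion failures?
#' @return data.frame with one row per run: `i0`, `i1` (1-based row
#'   indices into `met`) and `n_tol` (absorbed frames in the run); NULL if
#'   no frame qualifies.
#' @examples
#' m <- matrix(TRUE, 8, 3); m[4, 2] <- FALSE   # one isolated speed failure
#' segmentQualifyingRuns(m)          # one run covering all 8 frames
#' segmentQualifyingRuns(m, FALSE)   # split: 1-3 and 5-8
#' @export
segmentQualifyingRuns <- function(met, tolerance = TRUE) {
  stopifnot(is.matrix(met), ncol(met) == 3L, is.logical(met))
  n <- nrow(met)
  nmet <- rowSums(met)
  all3 <- nmet == 3L
  absorbed <- rep(FALSE, n)
  if (tolerance && n >= 3L) {
    inner <- 2:(n - 1L)
    absorbed[inner] <- !all3[inner] & nmet[inner] == 2L &
      all3[inner - 1L] & all3[inner + 1L]
  }
  qual <- all3 | absorbed
  if (!any(qual)) return(NULL)
  r <- rle(qual)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(i0 = starts[keep], i1 = ends[keep],
             n_tol = vapply(keep, function(k)
               sum(absorbed[starts[k]:ends[k]]), integer(1)))
}

#' Detect interaction events for one NK-DC pair
#'
#' Segments the frames shared by an NK and a DC track into interaction
#' events: maximal runs of consecutive frames on which the distance, speed
#' and confinement criteria hold simultaneously. When tolerance is enabled,
#' an interior frame at which exactly one criterion fails, with both
#' neighbours fully qualifying, is absorbed into the run (it counts in
#' `n_frames` and is tallied in `n_tolerated_frames`); two or more
#' consecutive failing frames always split the run, as do gaps (missing
#' frames) in either track. Event duration is `n_frames * frameIntervalS`,
#' so a planted k-frame contact recovers k frame intervals exactly.
#'
#' @param nk NK [Trajectory-class] (>= 2 points).
#' @param dc DC [Trajectory-class].
#' @param vFov numeric(1) or [FovSpeedSummary-class], the FOV-average speed
#'   the speed criterion is relative to.
#' @param config a [DetectorConfig-class].
#' @param frameIntervalS numeric(1), seconds per frame (used for durations).
#' @return data.frame of events sorted by `start_frame`, with columns
#'   `fov_id` (NA here; filled by [detectAll()]), `condition`, `nk_id`,
#'   `dc_id`, `start_frame`, `end_frame`, `n_frames`,
#'   `n_tolerated_frames`, `duration_s`, `class`.
#' @seealso [detectAll()], [distanceOnlyEvents()]
#' @export
detectEvents <- function(nk, dc, vFov, config = DetectorConfig(),
                         frameIntervalS = 30) {
  pd <- pairDistance(nk, dc, d = config@distanceThresholdUm)
  if (!nrow(pd)) return(.emptyEvents())
  sp <- instantaneousSpeed(nk)
  cs <- confinementRatio(nk)
  vShared <- sp$v_um_min[match(pd$frame, sp$frame)]
  crShared <- cs$cr[match(pd$frame, cs$frame)]
  cSpeed <- speedCriterion(vShared, vFov, config@speedFraction)
  ## against the previous shared frame; the pair's first shared frame is FALSE
  cConf <- confinementCriterion(crShared, config@crTolerance)

  ## split shared frames into blocks of consecutive frame indices:
  ## gaps (missing frames) always break runs
  brk <- c(0L, which(diff(pd$frame) > 1L), nrow(pd))
  out <- list()
  for (b in seq_len(length(brk) - 1L)) {
    idx <- (brk[b] + 1L):brk[b + 1L]
    met <- cbind(pd$dist_met[idx], cSpeed[idx], cConf[idx])
    runs <- segmentQualifyingRuns(met, config@toleranceEnabled)
    if (is.null(runs)) next
    fr <- pd$frame[idx]
    out[[length(out) + 1L]] <- data.frame(
      start_frame = fr[runs$i0], end_frame = fr[runs$i1],
      n_frames = runs$i1 - runs$i0 + 1L,
      n_tolerated_frames = runs$n_tol)
  }
  if (!length(out)) return(.emptyEvents())
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$start_frame), , drop = FALSE]
  ev$duration_s <- ev$n_frames * frameIntervalS
  data.frame(fov_id = NA_character_, condition = NA_character_,
             nk_id = nk@cellId, dc_id = dc@cellId, ev,
             class = classifyEvent(ev$duration_s, config),
             row.names = NULL)
}

#' Classify event durations
#'
#' Maps event durations to interaction classes: `touch_and_go` for
#' durations strictly below the touch-and-go threshold (printed < 5 s),
#' `long` for durations at or above the long threshold (>= 900 s, i.e.
#' >= 15 min), `intermediate` otherwise.
#'
#' @param durationS numeric vector of event durations in seconds.
#' @param config a [DetectorConfig-class].
#' @return character vector of class labels.
#' @examples
#' classifyEvent(c(4, 300, 930), DetectorConfig())
#' @export
classifyEvent <- function(durationS, config = DetectorConfig()) {
  ifelse(durationS < config@touchAndGoS, "touch_and_go",
         ifelse(durationS >= config@longThresholdS, "long", "intermediate"))
}

#' Detect interaction events across a field of view
#'
#' Runs [detectEvents()] over every NK x DC pair of the field of view,
#' using [fovAverageSpeed()] as the base of the speed criterion. An NK cell
#' may hold simultaneous events with different DCs; no tie-breaking
#' suppression is applied. Pairs whose tracks can never come within twice
#' the distance threshold (assessed by a conservative per-axis bounding-box
#' gap) are skipped as an optimization; gating cannot change the result
#' because such pairs never satisfy the distance criterion.
#'
#' @param fov a [FieldOfView-class] with at least one NK and one DC track.
#' @param config a [DetectorConfig-class].
#' @param gate logical(1); disable to force evaluation of every pair
#'   (results are identical, useful for self-checks).
#' @param speedCellTypes cell types entering the FOV-average speed
#'   (default `"NK"`).
#' @return data.frame of events (see [detectEvents()]) with `fov_id` and
#'   `condition` filled, ordered by (`nk_id`, `dc_id`, `start_frame`).
#' @rdname detectAll
#' @export
setMethod("detectAll", "FieldOfView",
          function(fov, config = DetectorConfig(), gate = TRUE,
                   speedCellTypes = "NK") {
  trjs <- fov@trajectories
  nks <- Filter(function(t) t@cellType == "NK" && nrow(t@points) >= 2L, trjs)
  dcs <- Filter(function(t) t@cellType == "DC", trjs)
  if (!length(nks)) stop("FOV ", fov@fovId, " has no NK track with >= 2 points")
  if (!length(dcs)) stop("FOV ", fov@fovId, " has no DC track")
  vs <- fovAverageSpeed(fov, cellTypes = speedCellTypes)
  twoD <- 2 * config@distanceThresholdUm
  bbox <- function(t) {
    p <- t@points
    c(min(p$x_um), max(p$x_um), min(p$y_um), max(p$y_um),
      min(p$z_um), max(p$z_um))
  }
  nkBox <- lapply(nks, bbox); dcBox <- lapply(dcs, bbox)
  axisGap <- function(a, b) {
    g <- function(lo1, hi1, lo2, hi2) max(0, lo2 - hi1, lo1 - hi2)
    sqrt(g(a[1], a[2], b[1], b[2])^2 + g(a[3], a[4], b[3], b[4])^2 +
           g(a[5], a[6], b[5], b[6])^2)
  }
  out <- list()
  for (nk in nks) for (dc in dcs) {
    if (gate &&
        axisGap(nkBox[[nk@cellId]], dcBox[[dc@cellId]]) > twoD) next
    ev <- detectEvents(nk, dc, vs, config, frameIntervalS = fov@frameIntervalS)
    if (nrow(ev)) out[[length(out) + 1L]] <- ev
  }
  if (!length(out)) return(.emptyEvents())
  ev <- do.call(rbind, out)
  ev$fov_id <- fov@fovId
  ev$condition <- fov@condition
  ev <- ev[order(ev$nk_id, ev$dc_id, ev$start_frame), , drop = FALSE]
  rownames(ev) <- NULL
  ev
})

#' Distance-only interaction baseline
#'
#' The simplified comparison algorithm that uses the NK-DC distance alone:
#' a per-frame on/off indicator (on iff Dist(t_i) <= d) and the naive
#' events given by its maximal on-runs over consecutive frames. This
#' baseline over-calls interactions (e.g. an NK cell passing a DC at high
#' speed within d), which is what the three-criterion detector corrects.
#' `t_on_off` carries plot values -1 (on) / 0 (off) for criterion
#' timelines.
#'
#' @param nk,dc [Trajectory-class] objects.
#' @param d distance threshold in micrometres (default 25).
#' @param frameIntervalS seconds per frame, used for naive durations.
#' @return list with `series` (data.frame `frame`, `dist_um`, `on`,
#'   `t_on_off`) and `events` (data.frame `start_frame`, `end_frame`,
#'   `n_frames`, `duration_s`).
#' @export
distanceOnlyEvents <- function(nk, dc, d = 25, frameIntervalS = 30) {
  pd <- pairDistance(nk, dc, d = d)
  series <- data.frame(frame = pd$frame, dist_um = pd$dist_um,
                       on = pd$dist_met, t_on_off = ifelse(pd$dist_met, -1, 0))
  empty <- data.frame(start_frame = integer(), end_frame = integer(),
                      n_frames = integer(), duration_s = numeric())
  if (!nrow(pd)) return(list(series = series, events = empty))
  brk <- c(0L, which(diff(pd$frame) > 1L), nrow(pd))
  out <- list()
  for (b in seq_len(length(brk) - 1L)) {
    idx <- (brk[b] + 1L):brk[b + 1L]
    r <- rle(pd$dist_met[idx])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) next
    fr <- pd$frame[idx]
    out[[length(out) + 1L]] <- data.frame(
      start_frame = fr[starts[keep]], end_frame = fr[ends[keep]],
      n_frames = ends[keep] - starts[keep] + 1L)
  }
  if (!length(out)) return(list(series = series, events = empty))
  ev <- do.call(rbind, out)
  ev <- ev[order(ev$start_frame), , drop = FALSE]
  ev$duration_s <- ev$n_frames * frameIntervalS
  rownames(ev) <- NULL
  list(series = series, events = ev)
}

#' Per-pair criterion diagnostics
#'
#' The full per-frame diagnostic table for one NK-DC pair, sufficient to
#' redraw criterion-timeline plots: distance (raw and digitized), speed
#' (raw and normalized), confinement ratio, and each criterion's boolean.
#'
#' @param nk,dc [Trajectory-class] objects.
#' @param vFov numeric(1) or [FovSpeedSummary-class].
#' @param config a [DetectorConfig-class].
#' @return data.frame with one row per shared frame: `frame`, `dist_um`,
#'   `dist_met`, `dist_d`, `v_um_min`, `v_norm`, `speed_met`, `cr`,
#'   `cr_met`.
#' @export
pairDiagnostics <- function(nk, dc, vFov, config = DetectorConfig()) {
  pd <- pairDistance(nk, dc, d = config@distanceThresholdUm)
  if (!nrow(pd))
    return(data.frame(frame = integer(), dist_um = numeric(),
                      dist_met = logical(), dist_d = numeric(),
                      v_um_min = numeric(), v_norm = numeric(),
                      speed_met = logical(), cr = numeric(),
                      cr_met = logical()))
  ns <- normalizedSpeed(nk, vFov, config@speedFraction)
  cs <- confinementRatio(nk)
  v <- ns$v_um_min[match(pd$frame, ns$frame)]
  vn <- ns$v_norm[match(pd$frame, ns$frame)]
  cr <- cs$cr[match(pd$frame, cs$frame)]
  crMet <- confinementCriterion(cr, config@crTolerance)
  data.frame(frame = pd$frame, dist_um = pd$dist_um, dist_met = pd$dist_met,
             dist_d = pd$dist_d, v_um_min = v, v_norm = vn,
             speed_met = speedCriterion(v, vFov, config@speedFraction),
             cr = cr, cr_met = crMet)
}
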
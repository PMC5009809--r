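#' @include AllClasses.R AllGenerics.R
NULL

.stepLengths <- function(p) {
  d <- diff(as.matrix(p[, c("x_um", "y_um", "z_um")]))
  sqrt(rowSums(d * d))
}

#' Instantaneous speed series of a track
#'
#' Per-frame instantaneous 3D speed: the step length between consecutive
#' observed positions divided by the elapsed time, in micrometres per
#' minute. The first frame has no preceding step; its speed is defined to
#' copy the first computed value so criterion series stay full-length.
#'
#' @param track a [Trajectory-class] with at least 2 points.
#' @return data.frame with columns `frame`, `time_s`, `v_um_min`.
#' @examples
#' trj <- Trajectory("NK1", "NK", 0:2, x = c(0, 10, 20), y = 0, z = 0,
#'                   timeS = c(0, 60, 120))
#' instantaneousSpeed(trj)   # 10 um/min at every frame
#' @export
instantaneousSpeed <- function(track) {
  p <- track@points
  if (nrow(p) < 2L)
    stop("instantaneousSpeed requires a track with at least 2 points")
  dt <- diff(p$time_s)
  if (any(dt <= 0)) stop("track times must be strictly increasing")
  v <- .stepLengths(p) / dt * 60
  data.frame(frame = p$frame, time_s = p$time_s, v_um_min = c(v[1L], v))
}

#' Cumulative trace length up to a frame
#'
#' Sum of consecutive 3D step lengths from the first observed frame through
#' `uptoFrame` (a frame index present in the track), in micrometres.
#'
#' @param track a [Trajectory-class].
#' @param uptoFrame frame index (as stored in the track) to accumulate to.
#' @return numeric(1), micrometres; 0 at the first frame.
#' @export
traceLength <- function(track, uptoFrame) {
  p <- track@points
  i <- match(uptoFrame, p$frame)
  if (is.na(i)) stop("uptoFrame ", uptoFrame, " not present in track")
  if (i == 1L) return(0)
  sum(.stepLengths(p[seq_len(i), , drop = FALSE]))
}

#' Confinement ratio series of a track
#'
#' The confinement ratio CR(t_i) is the net displacement from the track
#' start divided by the cumulative trace length at frame i: 1 for perfectly
#' straight motion, approaching 0 for confined motion. By convention
#' CR at the first frame is 1 (the 0/0 limit resolved toward "maximally
#' straight"); values are capped at 1 to absorb floating-point round-off in
#' the triangle inequality.
#'
#' @param track a [Trajectory-class] with at least 2 points.
#' @return data.frame with columns `frame`, `time_s`, `cr`, `trace_len_um`,
#'   `net_disp_um`.
#' @examples
#' sq <- Trajectory("NK1", "NK", 0:4, x = c(0, 10, 10, 0, 0),
#'                  y = c(0, 0, 10, 10, 0), z = 0, timeS = (0:4) * 30)
#' confinementRatio(sq)$cr   # ends at 0: closed loop
#' @export
confinementRatio <- function(track) {
  p <- track@points
  if (nrow(p) < 2L)
    stop("confinementRatio requires a track with at least 2 points")
  L <- c(0, cumsum(.stepLengths(p)))
  xyz <- as.matrix(p[, c("x_um", "y_um", "z_um")])
  d0 <- sweep(xyz, 2L, xyz[1L, ])
  R <- sqrt(rowSums(d0 * d0))
  cr <- ifelse(L > 0, pmin(R / L, 1), 1)
  data.frame(frame = p$frame, time_s = p$time_s, cr = cr,
             trace_len_um = L, net_disp_um = R)
}

#' Mean 3D speed of a track
#'
#' Arithmetic mean of the instantaneous speeds over frames i >= 1 (each
#' observed step counted once), in micrometres per minute. This is the
#' per-cell "3D velocity" used for cohort velocity distributions.
#'
#' @param track a [Trajectory-class] with at least 2 points.
#' @return numeric(1), um/min.
#' @export
meanTrackSpeed <- function(track) {
  p <- track@points
  if (nrow(p) < 2L)
    stop("meanTrackSpeed requires a track with at least 2 points")
  dt <- diff(p$time_s)
  if (any(dt <= 0)) stop("track times must be strictly increasing")
  mean(.stepLengths(p) / dt * 60)
}

#' Field-of-view average speed
#'
#' The base of the relative speed criterion: the mean over eligible tracks
#' of [meanTrackSpeed()] (a two-stage mean, so every cell weighs equally
#' regardless of track length). By default only NK tracks enter the
#' average, since dendritic cells are near-sessile; the cell-type set is
#' configurable and recorded in the returned summary.
#'
#' @param fov a [FieldOfView-class].
#' @param cellTypes character vector of cell types to average over
#'   (default `"NK"`).
#' @return A [FovSpeedSummary-class] with the FOV-average speed `vFov`,
#'   the per-track mean speeds, and the cell-type set used.
#' @rdname fovAverageSpeed
#' @export
setMethod("fovAverageSpeed", "FieldOfView", function(fov, cellTypes = "NK") {
  trjs <- Filter(function(t) t@cellType %in% cellTypes && nrow(t@points) >= 2L,
                 fov@trajectories)
  if (!length(trjs))
    stop("no eligible tracks (cell types ", paste(cellTypes, collapse = ", "),
         " with >= 2 points) in FOV ", fov@fovId)
  per <- vapply(trjs, meanTrackSpeed, numeric(1))
  new("FovSpeedSummary", vFov = mean(per), perTrack = per,
      cellTypes = cellTypes)
})

#' Normalized speed series
#'
#' The plot-level normalized speed v_Norm(t_i): 0 on frames where the speed
#' criterion is met (v(t_i) <= alpha * V_FOV, inclusive), otherwise
#' v(t_i)/V_FOV. The zero-set of v_Norm is exactly the speed-criterion-true
#' set, so the series digitizes the criterion while remaining plottable.
#'
#' @param track a [Trajectory-class] with at least 2 points.
#' @param vFov numeric(1) or [FovSpeedSummary-class]; FOV-average speed in
#'   um/min (> 0).
#' @param alpha speed fraction in (0, 1), default 0.60.
#' @return data.frame with columns `frame`, `time_s`, `v_um_min`, `v_norm`.
#' @export
normalizedSpeed <- function(track, vFov, alpha = 0.60) {
  if (is(vFov, "FovSpeedSummary")) vFov <- vFov@vFov
  if (!is.numeric(vFov) || length(vFov) != 1L || vFov <= 0)
    stop("vFov must be a single positive speed (um/min)")
  sp <- instantaneousSpeed(track)
  met <- speedCriterion(sp$v_um_min, vFov, alpha)
  sp$v_norm <- ifelse(met, 0, sp$v_um_min / vFov)
  sp
}
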
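#' @import methods
NULL

## Column schema of the track table (CSV) and of the points slot.
.TRACK_COLUMNS <- c("fov_id", "condition", "cell_id", "cell_type",
                    "frame", "time_s", "x_um", "y_um", "z_um")
.POINT_COLUMNS <- c("frame", "time_s", "x_um", "y_um", "z_um")
.CELL_TYPES <- c("NK", "DC", "T")

#' Trajectory: one cell's ordered 3D positions over time
#'
#' A `Trajectory` holds the track of a single cell within one field of view:
#' an ordered table of time points with centroid coordinates in micrometres.
#' Frames are sorted at construction; scientific invariants (at least two
#' points, strictly increasing frames and times, no duplicates) are checked
#' by [validateFov()], which reports findings rather than raising errors, so
#' that imperfect real-world exports can still be loaded and triaged.
#'
#' @slot cellId character(1), unique within a field of view.
#' @slot cellType character(1), one of `"NK"`, `"DC"`, `"T"`.
#' @slot points data.frame with columns `frame` (non-negative integer),
#'   `time_s` (seconds from movie start), `x_um`, `y_um`, `z_um`.
#'
#' @seealso [FieldOfView-class], [validateFov()]
#' @exportClass Trajectory
setClass("Trajectory",
  representation(cellId = "character", cellType = "character",
                 points = "data.frame"),
  prototype(cellId = NA_character_, cellType = "NK",
            points = data.frame(frame = integer(), time_s = numeric(),
                                x_um = numeric(), y_um = numeric(),
                                z_um = numeric()))
)

setValidity("Trajectory", function(object) {
  msg <- character()
  if (length(object@cellId) != 1L || is.na(object@cellId) ||
      !nzchar(object@cellId))
    msg <- c(msg, "cellId must be a single non-empty string")
  if (length(object@cellType) != 1L || !object@cellType %in% .CELL_TYPES)
    msg <- c(msg, sprintf("cellType must be one of %s",
                          paste(.CELL_TYPES, collapse = ", ")))
  p <- object@points
  if (!all(.POINT_COLUMNS %in% names(p)))
    msg <- c(msg, sprintf("points must have columns %s",
                          paste(.POINT_COLUMNS, collapse = ", ")))
  else {
    if (!is.numeric(p$frame) || any(p$frame < 0, na.rm = TRUE))
      msg <- c(msg, "frame must be a non-negative integer index")
    if (is.unsorted(p$frame))
      msg <- c(msg, "points must be sorted by frame")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Trajectory
#'
#' @param cellId character(1) cell identifier, unique within the field of view.
#' @param cellType `"NK"`, `"DC"` or `"T"`.
#' @param frame integer vector of frame indices (0-based or as exported).
#' @param x,y,z numeric coordinates in micrometres.
#' @param timeS numeric times in seconds; if `NULL`, filled downstream from
#'   the field-of-view frame interval (`frame * frameIntervalS`).
#'
#' @return A [Trajectory-class] object with points sorted by frame.
#' @examples
#' trj <- Trajectory("NK1", "NK", frame = 0:2, x = c(0, 5, 10),
#'                   y = 0, z = 0, timeS = c(0, 30, 60))
#' nPoints(trj)
#' @export
Trajectory <- function(cellId, cellType, frame, x, y, z, timeS = NULL) {
  n <- length(frame)
  if (is.null(timeS)) timeS <- rep(NA_real_, n)
  p <- data.frame(frame = as.integer(frame), time_s = as.numeric(timeS),
                  x_um = rep_len(as.numeric(x), n),
                  y_um = rep_len(as.numeric(y), n),
                  z_um = rep_len(as.numeric(z), n))
  p <- p[order(p$frame), , drop = FALSE]
  rownames(p) <- NULL
  new("Trajectory", cellId = as.character(cellId),
      cellType = as.character(cellType), points = p)
}

#' FieldOfView: co-registered trajectories sharing one frame clock
#'
#' A `FieldOfView` is one imaged lymph-node volume over one movie: a set of
#' [Trajectory-class] objects sharing a condition label and a nominal frame
#' interval. All per-movie computations (FOV-average speed, pairwise
#' NK-DC detection) operate on this container.
#'
#' @slot fovId character(1) field-of-view identifier.
#' @slot condition character(1) condition label, e.g. `"steady_state"` or
#'   `"LPS"` (free labels are allowed).
#' @slot frameIntervalS numeric(1), nominal seconds between frames (> 0).
#' @slot trajectories named list of [Trajectory-class], keyed by cell id.
#'
#' @exportClass FieldOfView
setClass("FieldOfView",
  representation(fovId = "character", condition = "character",
                 frameIntervalS = "numeric", trajectories = "list"),
  prototype(fovId = NA_character_, condition = "steady_state",
            frameIntervalS = 30, trajectories = list())
)

setValidity("FieldOfView", function(object) {
  msg <- character()
  if (length(object@fovId) != 1L || is.na(object@fovId))
    msg <- c(msg, "fovId must be a single string")
  if (length(object@frameIntervalS) != 1L || !is.finite(object@frameIntervalS) ||
      object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be a single positive number")
  if (length(object@trajectories)) {
    ok <- vapply(object@trajectories, is, logical(1), class2 = "Trajectory")
    if (!all(ok)) msg <- c(msg, "trajectories must all be Trajectory objects")
    else {
      ids <- vapply(object@trajectories, function(t) t@cellId, character(1))
      if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate cell_id within FOV: %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FieldOfView
#'
#' @param fovId character(1) identifier.
#' @param trajectories list of [Trajectory-class] objects.
#' @param condition condition label (default `"steady_state"`).
#' @param frameIntervalS nominal frame spacing in seconds.
#' @return A [FieldOfView-class]; trajectories are named by cell id and
#'   missing `time_s` values are filled as `frame * frameIntervalS`.
#' @examples
#' nk <- Trajectory("NK1", "NK", 0:2, x = c(0, 5, 10), y = 0, z = 0)
#' dc <- Trajectory("DC1", "DC", 0:2, x = 3, y = 4, z = 0)
#' fov <- FieldOfView("fov1", list(nk, dc), frameIntervalS = 30)
#' @export
FieldOfView <- function(fovId, trajectories = list(),
                        condition = "steady_state", frameIntervalS = 30) {
  trajectories <- lapply(trajectories, function(t) {
    na <- is.na(t@points$time_s)
    if (any(na)) t@points$time_s[na] <- t@points$frame[na] * frameIntervalS
    t
  })
  names(trajectories) <- vapply(trajectories, function(t) t@cellId, character(1))
  new("FieldOfView", fovId = as.character(fovId),
      condition = as.character(condition),
      frameIntervalS = as.numeric(frameIntervalS),
      trajectories = trajectories)
}

#' DetectorConfig: parameters of the three-criterion interaction detector
#'
#' Holds the detector thresholds. Defaults are the published operating
#' point: NK-DC centroid distance d <= 25 um (inclusive), NK speed at most
#' 60% of the field-of-view average speed (inclusive), confinement ratio
#' non-increasing frame to frame up to a small tolerance, long interactions
#' at >= 900 s and touch-and-go interactions at < 5 s. With
#' `toleranceEnabled`, an interior frame of a qualifying run at which
#' exactly one criterion fails (both neighbours fully qualifying) is
#' absorbed into the run.
#'
#' @slot distanceThresholdUm numeric(1), d in micrometres (default 25).
#' @slot speedFraction numeric(1) in (0, 1), the fraction of the FOV-average
#'   speed below which a frame meets the speed criterion (default 0.60).
#' @slot crTolerance numeric(1), dimensionless slack on the frame-to-frame
#'   confinement-ratio non-increase (default 0.01).
#' @slot longThresholdS numeric(1), seconds; events at least this long are
#'   classed `long` (default 900).
#' @slot touchAndGoS numeric(1), seconds; events strictly shorter are
#'   classed `touch_and_go` (default 5).
#' @slot toleranceEnabled logical(1), single-frame single-parameter
#'   absorption (default TRUE).
#'
#' @exportClass DetectorConfig
setClass("DetectorConfig",
  representation(distanceThresholdUm = "numeric", speedFraction = "numeric",
                 crTolerance = "numeric", longThresholdS = "numeric",
                 touchAndGoS = "numeric", toleranceEnabled = "logical"),
  prototype(distanceThresholdUm = 25, speedFraction = 0.60,
            crTolerance = 0.01, longThresholdS = 900, touchAndGoS = 5,
            toleranceEnabled = TRUE)
)

setValidity("DetectorConfig", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@distanceThresholdUm) || object@distanceThresholdUm <= 0)
    msg <- c(msg, "distanceThresholdUm must be a single positive number")
  if (!num1(object@speedFraction) || object@speedFraction <= 0 ||
      object@speedFraction >= 1)
    msg <- c(msg, "speedFraction must be in (0, 1)")
  if (!num1(object@crTolerance) || object@crTolerance <= 0)
    msg <- c(msg, "crTolerance must be a single positive number")
  if (!num1(object@longThresholdS) || object@longThresholdS <= 0)
    msg <- c(msg, "longThresholdS must be a single positive number")
  if (!num1(object@touchAndGoS) || object@touchAndGoS <= 0)
    msg <- c(msg, "touchAndGoS must be a single positive number")
  if (num1(object@touchAndGoS) && num1(object@longThresholdS) &&
      object@touchAndGoS >= object@longThresholdS)
    msg <- c(msg, "touchAndGoS must be smaller than longThresholdS")
  if (length(object@toleranceEnabled) != 1L || is.na(object@toleranceEnabled))
    msg <- c(msg, "toleranceEnabled must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a DetectorConfig
#'
#' @param distanceThresholdUm distance threshold d in micrometres.
#' @param speedFraction fraction of the FOV-average speed (0 < alpha < 1).
#' @param crTolerance confinement-ratio non-increase tolerance.
#' @param longThresholdS long-interaction threshold in seconds.
#' @param touchAndGoS touch-and-go threshold in seconds.
#' @param toleranceEnabled absorb isolated single-criterion failures?
#' @return A validated [DetectorConfig-class].
#' @examples
#' DetectorConfig()
#' DetectorConfig(distanceThresholdUm = 30)
#' @export
DetectorConfig <- function(distanceThresholdUm = 25, speedFraction = 0.60,
                           crTolerance = 0.01, longThresholdS = 900,
                           touchAndGoS = 5, toleranceEnabled = TRUE) {
  new("DetectorConfig",
      distanceThresholdUm = as.numeric(distanceThresholdUm),
      speedFraction = as.numeric(speedFraction),
      crTolerance = as.numeric(crTolerance),
      longThresholdS = as.numeric(longThresholdS),
      touchAndGoS = as.numeric(touchAndGoS),
      toleranceEnabled = as.logical(toleranceEnabled))
}

#' FovSpeedSummary: the field-of-view average speed
#'
#' The base of the relative speed criterion: the mean over eligible tracks
#' of each track's mean instantaneous 3D speed, in micrometres per minute.
#'
#' @slot vFov numeric(1), FOV-average speed in um/min.
#' @slot perTrack named numeric, per-track mean speeds.
#' @slot cellTypes character, the cell types averaged over.
#' @exportClass FovSpeedSummary
setClass("FovSpeedSummary",
  representation(vFov = "numeric", perTrack = "numeric",
                 cellTypes = "character"),
  prototype(vFov = NA_real_, perTrack = numeric(), cellTypes = "NK")
)

#' SimulationConfig: parameters of the synthetic track generator
#'
#' Defines one simulated imaging experiment: fast persistent-random-walk NK
#' (and T) cells, quasi-static dendritic cells drifting around fixed
#' anchors, and optionally a table of planted contact episodes in which an
#' NK cell approaches its DC, dwells within a controlled distance at a
#' controlled (slow) speed with non-increasing confinement ratio, and then
#' departs. Planted dwell parameters sit strictly inside the detector
#' thresholds, so episodes are detectable by construction.
#'
#' @slot seed integer(1) base seed; each FOV uses a stream derived from
#'   (seed, fovIndex) and is independently reproducible.
#' @slot nFrames integer(1) frames per movie.
#' @slot frameIntervalS numeric(1) seconds between frames.
#' @slot volumeUm numeric(3) imaged volume (x, y, z) in micrometres.
#' @slot nNk,nDc,nT integer(1) cells per field of view.
#' @slot nkSpeedMeanUmMin,nkSpeedSdUmMin numeric(1) between-track mean and
#'   sd of NK target speeds (um/min).
#' @slot nkSpeedWithinSdUmMin numeric(1) within-track per-frame speed sd.
#' @slot tSpeedMeanUmMin,tSpeedSdUmMin numeric(1) T-cell analogues.
#' @slot dcDriftUmMin numeric(1) dendritic-cell drift scale (um/min) of the
#'   mean-reverting wobble around each DC anchor.
#' @slot persistence numeric(1) in \[0, 1), directional persistence of the
#'   random walk headings.
#' @slot jitterSdUm numeric(1) localization jitter sd per coordinate.
#' @slot dropP numeric(1) in \[0, 1), per-cell per-frame drop probability.
#' @slot dcSeparationUm numeric(1); if > 0, DC anchors are displaced beyond
#'   the NK volume so that every NK-DC distance stays at least this value
#'   (used for null-specificity experiments).
#' @slot episodes data.frame of planted episodes with columns `nk_id`,
#'   `dc_id`, `start_frame`, `n_frames`, `dwell_dist_um`,
#'   `dwell_speed_frac`.
#' @slot condition character(1) condition label stamped on the output.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(seed = "integer", nFrames = "integer",
                 frameIntervalS = "numeric", volumeUm = "numeric",
                 nNk = "integer", nDc = "integer", nT = "integer",
                 nkSpeedMeanUmMin = "numeric", nkSpeedSdUmMin = "numeric",
                 nkSpeedWithinSdUmMin = "numeric",
                 tSpeedMeanUmMin = "numeric", tSpeedSdUmMin = "numeric",
                 dcDriftUmMin = "numeric", persistence = "numeric",
                 jitterSdUm = "numeric", dropP = "numeric",
                 dcSeparationUm = "numeric", episodes = "data.frame",
                 condition = "character"),
  prototype(seed = 1L, nFrames = 120L, frameIntervalS = 30,
            volumeUm = c(300, 300, 100), nNk = 20L, nDc = 8L, nT = 0L,
            nkSpeedMeanUmMin = 10, nkSpeedSdUmMin = 0.5,
            nkSpeedWithinSdUmMin = 0.5, tSpeedMeanUmMin = 10,
            tSpeedSdUmMin = 2, dcDriftUmMin = 0.5, persistence = 0.7,
            jitterSdUm = 0, dropP = 0, dcSeparationUm = 0,
            episodes = data.frame(nk_id = character(), dc_id = character(),
                                  start_frame = integer(),
                                  n_frames = integer(),
                                  dwell_dist_um = numeric(),
                                  dwell_speed_frac = numeric()),
            condition = "steady_state")
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@nFrames) || object@nFrames < 2L)
    msg <- c(msg, "nFrames must be >= 2")
  if (!num1(object@frameIntervalS) || object@frameIntervalS <= 0)
    msg <- c(msg, "frameIntervalS must be positive")
  if (length(object@volumeUm) != 3L || any(object@volumeUm <= 0))
    msg <- c(msg, "volumeUm must be 3 positive lengths")
  if (object@nNk < 0L || object@nDc < 0L || object@nT < 0L)
    msg <- c(msg, "cell counts must be non-negative")
  if (!num1(object@persistence) || object@persistence < 0 ||
      object@persistence >= 1)
    msg <- c(msg, "persistence must be in [0, 1)")
  if (!num1(object@jitterSdUm) || object@jitterSdUm < 0)
    msg <- c(msg, "jitterSdUm must be >= 0")
  if (!num1(object@dropP) || object@dropP < 0 || object@dropP >= 1)
    msg <- c(msg, "dropP must be in [0, 1)")
  if (object@nkSpeedMeanUmMin <= 0 || object@tSpeedMeanUmMin <= 0)
    msg <- c(msg, "mean speeds must be positive")
  ep <- object@episodes
  epCols <- c("nk_id", "dc_id", "start_frame", "n_frames",
              "dwell_dist_um", "dwell_speed_frac")
  if (!all(epCols %in% names(ep)))
    msg <- c(msg, sprintf("episodes must have columns %s",
                          paste(epCols, collapse = ", ")))
  else if (nrow(ep)) {
    nkIds <- sprintf("NK%03d", seq_len(object@nNk))
    dcIds <- sprintf("DC%03d", seq_len(object@nDc))
    if (!all(ep$nk_id %in% nkIds))
      msg <- c(msg, sprintf("episode references nonexistent NK cell: %s",
                            paste(setdiff(ep$nk_id, nkIds), collapse = ", ")))
    if (!all(ep$dc_id %in% dcIds))
      msg <- c(msg, sprintf("episode references nonexistent DC: %s",
                            paste(setdiff(ep$dc_id, dcIds), collapse = ", ")))
    if (any(ep$n_frames < 1L) || any(ep$start_frame < 1L))
      msg <- c(msg, "episodes need start_frame >= 1 and n_frames >= 1")
    if (any(ep$start_frame + ep$n_frames - 1L > object@nFrames - 1L))
      msg <- c(msg, "episode extends past the last frame")
    if (any(ep$dwell_speed_frac <= 0) || any(ep$dwell_dist_um <= 0))
      msg <- c(msg, "dwell parameters must be positive")
    for (id in unique(ep$nk_id)) {
      e <- ep[ep$nk_id == id, , drop = FALSE]
      if (nrow(e) > 1L) {
        e <- e[order(e$start_frame), ]
        if (any(e$start_frame[-1L] <= (e$start_frame + e$n_frames - 1L)[-nrow(e)]))
          msg <- c(msg, sprintf("overlapping episodes on NK cell %s", id))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed base random seed (integer).
#' @param nFrames frames per movie.
#' @param frameIntervalS frame spacing in seconds.
#' @param volumeUm numeric(3) imaged volume in micrometres.
#' @param nNk,nDc,nT cells per field of view.
#' @param nkSpeedMeanUmMin,nkSpeedSdUmMin,nkSpeedWithinSdUmMin NK speed
#'   distribution (um/min): between-track mean/sd and within-track sd.
#' @param tSpeedMeanUmMin,tSpeedSdUmMin T-cell speed distribution.
#' @param dcDriftUmMin DC drift scale in um/min.
#' @param persistence heading persistence in \[0, 1).
#' @param jitterSdUm localization jitter sd (um, per coordinate).
#' @param dropP per-cell per-frame drop probability.
#' @param dcSeparationUm enforced minimum NK-DC separation (0 = off).
#' @param episodes planted-episode data.frame (see
#'   [SimulationConfig-class]).
#' @param condition condition label.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- SimulationConfig(seed = 1, nNk = 5, nDc = 2)
#' @export
SimulationConfig <- function(seed = 1L, nFrames = 120L, frameIntervalS = 30,
                             volumeUm = c(300, 300, 100), nNk = 20L,
                             nDc = 8L, nT = 0L, nkSpeedMeanUmMin = 10,
                             nkSpeedSdUmMin = 0.5, nkSpeedWithinSdUmMin = 0.5,
                             tSpeedMeanUmMin = 10, tSpeedSdUmMin = 2,
                             dcDriftUmMin = 0.5, persistence = 0.7,
                             jitterSdUm = 0, dropP = 0, dcSeparationUm = 0,
                             episodes = NULL, condition = "steady_state") {
  if (is.null(episodes))
    episodes <- data.frame(nk_id = character(), dc_id = character(),
                           start_frame = integer(), n_frames = integer(),
                           dwell_dist_um = numeric(),
                           dwell_speed_frac = numeric())
  new("SimulationConfig", seed = as.integer(seed),
      nFrames = as.integer(nFrames), frameIntervalS = as.numeric(frameIntervalS),
      volumeUm = as.numeric(volumeUm), nNk = as.integer(nNk),
      nDc = as.integer(nDc), nT = as.integer(nT),
      nkSpeedMeanUmMin = as.numeric(nkSpeedMeanUmMin),
      nkSpeedSdUmMin = as.numeric(nkSpeedSdUmMin),
      nkSpeedWithinSdUmMin = as.numeric(nkSpeedWithinSdUmMin),
      tSpeedMeanUmMin = as.numeric(tSpeedMeanUmMin),
      tSpeedSdUmMin = as.numeric(tSpeedSdUmMin),
      dcDriftUmMin = as.numeric(dcDriftUmMin),
      persistence = as.numeric(persistence),
      jitterSdUm = as.numeric(jitterSdUm), dropP = as.numeric(dropP),
      dcSeparationUm = as.numeric(dcSeparationUm),
      episodes = as.data.frame(episodes), condition = as.character(condition))
}
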
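#' @include AllClasses.R
NULL

#' Accessors for track containers
#'
#' Small accessor generics for [Trajectory-class] and [FieldOfView-class]
#' objects; use these instead of reaching into slots.
#'
#' @param object a `Trajectory` or `FieldOfView`.
#' @param ... passed on to methods.
#' @return `cellId`, `cellType`, `fovId`, `condition` return character(1);
#'   `trackPoints` a data.frame of time points; `nPoints` integer(1);
#'   `frameInterval` numeric(1) seconds; `trajectories` a named list;
#'   `cellIds` a character vector (optionally filtered by cell type).
#' @name accessors
#' @examples
#' trj <- Trajectory("NK1", "NK", 0:2, x = c(0, 5, 10), y = 0, z = 0)
#' cellId(trj); cellType(trj); nPoints(trj)
NULL

#' @rdname accessors
#' @export
setGeneric("cellId", function(object) standardGeneric("cellId"))
#' @rdname accessors
#' @export
setGeneric("cellType", function(object) standardGeneric("cellType"))
#' @rdname accessors
#' @export
setGeneric("trackPoints", function(object) standardGeneric("trackPoints"))
#' @rdname accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))
#' @rdname accessors
#' @export
setGeneric("fovId", function(object) standardGeneric("fovId"))
#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("trajectories", function(object) standardGeneric("trajectories"))
#' @rdname accessors
#' @param cellTypes optional character vector restricting to cell types.
#' @export
setGeneric("cellIds", function(object, cellTypes = NULL) standardGeneric("cellIds"))

#' @rdname accessors
setMethod("cellId", "Trajectory", function(object) object@cellId)
#' @rdname accessors
setMethod("cellType", "Trajectory", function(object) object@cellType)
#' @rdname accessors
setMethod("trackPoints", "Trajectory", function(object) object@points)
#' @rdname accessors
setMethod("nPoints", "Trajectory", function(object) nrow(object@points))
#' @rdname accessors
setMethod("fovId", "FieldOfView", function(object) object@fovId)
#' @rdname accessors
setMethod("condition", "FieldOfView", function(object) object@condition)
#' @rdname accessors
setMethod("frameInterval", "FieldOfView", function(object) object@frameIntervalS)
#' @rdname accessors
setMethod("trajectories", "FieldOfView", function(object) object@trajectories)
#' @rdname accessors
setMethod("cellIds", "FieldOfView", function(object, cellTypes = NULL) {
  trjs <- object@trajectories
  if (!is.null(cellTypes)) {
    keep <- vapply(trjs, function(t) t@cellType %in% cellTypes, logical(1))
    trjs <- trjs[keep]
  }
  unname(vapply(trjs, function(t) t@cellId, character(1)))
})

setMethod("show", "Trajectory", function(object) {
  p <- object@points
  cat(sprintf("Trajectory %s (%s): %d points", object@cellId,
              object@cellType, nrow(p)))
  if (nrow(p))
    cat(sprintf(", frames %d-%d, t = %.0f-%.0f s", min(p$frame), max(p$frame),
                min(p$time_s), max(p$time_s)))
  cat("\n")
})

setMethod("show", "FieldOfView", function(object) {
  types <- table(vapply(object@trajectories, function(t) t@cellType,
                        character(1)))
  cat(sprintf("FieldOfView %s [%s], frame interval %.1f s\n", object@fovId,
              object@condition, object@frameIntervalS))
  cat(sprintf("  %d trajectories (%s)\n", length(object@trajectories),
              if (length(types)) paste(sprintf("%s: %d", names(types), types),
                                       collapse = ", ") else "empty"))
})

setMethod("show", "DetectorConfig", function(object) {
  cat("DetectorConfig\n")
  cat(sprintf("  distance threshold d: %.1f um (inclusive)\n",
              object@distanceThresholdUm))
  cat(sprintf("  speed fraction alpha: %.2f of FOV-average speed\n",
              object@speedFraction))
  cat(sprintf("  CR non-increase tolerance: %.3g\n", object@crTolerance))
  cat(sprintf("  classes: touch_and_go < %.0f s <= intermediate < %.0f s <= long\n",
              object@touchAndGoS, object@longThresholdS))
  cat(sprintf("  single-frame tolerance: %s\n",
              if (object@toleranceEnabled) "enabled" else "disabled"))
})

setMethod("show", "FovSpeedSummary", function(object) {
  cat(sprintf("FovSpeedSummary: V_FOV = %.3f um/min over %d tracks (%s)\n",
              object@vFov, length(object@perTrack),
              paste(object@cellTypes, collapse = ", ")))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig (seed %d): %d frames @ %.0f s, volume %s um\n",
              object@seed, object@nFrames, object@frameIntervalS,
              paste(object@volumeUm, collapse = " x ")))
  cat(sprintf("  cells: %d NK, %d DC, %d T; NK speed %.1f +/- %.1f um/min\n",
              object@nNk, object@nDc, object@nT, object@nkSpeedMeanUmMin,
              object@nkSpeedSdUmMin))
  cat(sprintf("  jitter sd %.2f um, drop p %.2f, planted episodes: %d\n",
              object@jitterSdUm, object@dropP, nrow(object@episodes)))
})

#' @rdname fovAverageSpeed
#' @export
setGeneric("fovAverageSpeed",
           function(fov, cellTypes = "NK") standardGeneric("fovAverageSpeed"))

#' @rdname detectAll
#' @export
setGeneric("detectAll", function(fov, config = DetectorConfig(), ...)
  standardGeneric("detectAll"))

#' @rdname validateFov
#' @export
setGeneric("validateFov", function(fov) standardGeneric("validateFov"))
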
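#' @include AllClasses.R AllGenerics.R
NULL

#' Read a track table
#'
#' Reads a CSV export of 3D cell tracks (one row per cell per frame) and
#' groups it into [FieldOfView-class] objects. The required columns are
#' `fov_id, condition, cell_id, cell_type, frame, time_s, x_um, y_um, z_um`
#' (UTF-8, '.' decimal point). Points are sorted by frame within each cell;
#' the frame interval of each FOV is inferred as the median per-frame time
#' gap (`diff(time_s)/diff(frame)` over consecutive points), which is
#' invariant to row order and robust to dropped frames. Missing `time_s`
#' values are filled as `frame * frameIntervalS`.
#'
#' Structural problems that make rows uninterpretable (missing or unknown
#' columns, non-numeric coordinates, time decreasing within a cell) raise
#' errors naming the column, row or cell. Scientific invariant violations
#' (duplicate frames, single-point tracks, frame gaps) are left to
#' [validateFov()], which reports findings.
#'
#' @param path path to the CSV file.
#' @param frameIntervalS optional numeric(1) overriding the inferred frame
#'   interval (required if the file carries no usable times).
#' @return A named list of [FieldOfView-class] objects, keyed by `fov_id`.
#' @seealso [writeTracks()], [validateFov()]
#' @export
readTracks <- function(path, frameIntervalS = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  missing <- setdiff(.TRACK_COLUMNS, names(raw))
  if (length(missing))
    stop("track table format error: missing column(s) ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(names(raw), .TRACK_COLUMNS)
  if (length(unknown))
    stop("track table format error: unknown column(s) ",
         paste(unknown, collapse = ", "))
  numCols <- c("frame", "time_s", "x_um", "y_um", "z_um")
  for (cc in numCols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) & !(raw[[cc]] %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("parse error in column '%s' at file row %d: '%s'",
                   cc, bad[1L] + 1L, raw[[cc]][bad[1L]]))
    if (cc != "time_s" && anyNA(v))
      stop(sprintf("parse error: empty value in column '%s' at file row %d",
                   cc, which(is.na(v))[1L] + 1L))
    raw[[cc]] <- v
  }
  badType <- setdiff(unique(raw$cell_type), .CELL_TYPES)
  if (length(badType))
    stop("track table format error: unknown cell_type ",
         paste(badType, collapse = ", "))

  fovs <- list()
  for (fid in unique(raw$fov_id)) {
    sub <- raw[raw$fov_id == fid, , drop = FALSE]
    cond <- unique(sub$condition)
    if (length(cond) > 1L)
      stop(sprintf("FOV %s carries multiple condition labels: %s", fid,
                   paste(cond, collapse = ", ")))
    trjs <- list()
    gaps <- numeric()
    for (cid in unique(sub$cell_id)) {
      rows <- sub[sub$cell_id == cid, , drop = FALSE]
      ctype <- unique(rows$cell_type)
      if (length(ctype) > 1L)
        stop(sprintf("cell %s in FOV %s has multiple cell_type values", cid, fid))
      ord <- order(rows$frame)
      rows <- rows[ord, , drop = FALSE]
      ts <- rows$time_s[!is.na(rows$time_s)]
      if (length(ts) > 1L && any(diff(ts) < 0))
        stop(sprintf("validation error: non-monotonic time within cell %s (FOV %s)",
                     cid, fid))
      if (nrow(rows) > 1L) {
        df <- diff(rows$frame); dt <- diff(rows$time_s)
        ok <- df > 0 & is.finite(dt)
        gaps <- c(gaps, dt[ok] / df[ok])
      }
      trjs[[cid]] <- Trajectory(cid, ctype, rows$frame, rows$x_um,
                                rows$y_um, rows$z_um, timeS = rows$time_s)
    }
    dtS <- if (!is.null(frameIntervalS)) frameIntervalS
           else if (length(gaps)) stats::median(gaps)
           else stop(sprintf(
             "FOV %s: cannot infer frame interval (no timed multi-point track); supply frameIntervalS",
             fid))
    fovs[[fid]] <- FieldOfView(fid, trjs, condition = cond,
                               frameIntervalS = dtS)
  }
  fovs
}

#' Write a track table
#'
#' Serializes fields of view to the standard track CSV with deterministic
#' row order (`fov_id`, `cell_id`, `frame`) and fixed-precision floats
#' (6 decimals for coordinates, 3 for time), so write/read round-trips are
#' value-stable.
#'
#' @param fovs a [FieldOfView-class] or list of them.
#' @param path output file path.
#' @return Invisibly, the number of rows written.
#' @seealso [readTracks()]
#' @export
writeTracks <- function(fovs, path) {
  if (is(fovs, "FieldOfView")) fovs <- list(fovs)
  rows <- lapply(fovs, function(fov) {
    trjs <- fov@trajectories
    if (!length(trjs)) return(NULL)
    do.call(rbind, lapply(trjs, function(t) {
      p <- t@points
      data.frame(fov_id = fov@fovId, condition = fov@condition,
                 cell_id = t@cellId, cell_type = t@cellType,
                 frame = p$frame, time_s = p$time_s, x_um = p$x_um,
                 y_um = p$y_um, z_um = p$z_um)
    }))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(.TRACK_COLUMNS))),
      .TRACK_COLUMNS)
  else {
    tab <- tab[order(tab$fov_id, tab$cell_id, tab$frame), , drop = FALSE]
    tab$time_s <- sprintf("%.3f", tab$time_s)
    for (cc in c("x_um", "y_um", "z_um")) tab[[cc]] <- sprintf("%.6f", tab[[cc]])
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(nrow(tab))
}

#' Validate a field of view
#'
#' Checks the scientific invariants of a [FieldOfView-class] and its
#' trajectories and returns one finding per violation instead of raising
#' errors, so imperfect data can be triaged. Errors (`severity = "error"`):
#' fewer than 2 points, duplicate frames, non-increasing times, non-finite
#' coordinates, inter-frame time gaps inconsistent with the FOV frame clock.
#' Informational findings (`severity = "info"`): missing frames (gaps),
#' which the detector handles by breaking runs.
#'
#' @param fov a [FieldOfView-class].
#' @return A data.frame with columns `cell_id`, `frame`, `severity`,
#'   `message`; zero rows iff all invariants hold.
#' @rdname validateFov
#' @export
setMethod("validateFov", "FieldOfView", function(fov) {
  finding <- function(cell, frame, severity, message)
    data.frame(cell_id = cell, frame = frame, severity = severity,
               message = message)
  out <- list()
  dtS <- fov@frameIntervalS
  for (t in fov@trajectories) {
    p <- t@points
    id <- t@cellId
    if (nrow(p) < 2L)
      out[[length(out) + 1L]] <- finding(id, NA_integer_, "error",
                                         "fewer than 2 points")
    dup <- unique(p$frame[duplicated(p$frame)])
    for (f in dup)
      out[[length(out) + 1L]] <- finding(id, f, "error",
                                         sprintf("duplicate frame %d", f))
    if (nrow(p) > 1L) {
      dt <- diff(p$time_s)
      bad <- which(dt <= 0 & diff(p$frame) > 0)
      for (i in bad)
        out[[length(out) + 1L]] <- finding(id, p$frame[i + 1L], "error",
                                           "time not strictly increasing")
      df <- diff(p$frame)
      ratio <- dt / (df * dtS)
      off <- which(df > 0 & abs(ratio - 1) > 0.05)
      for (i in off)
        out[[length(out) + 1L]] <- finding(
          id, p$frame[i + 1L], "error",
          sprintf("inter-frame time %.3f s inconsistent with frame clock (%.3f s x %d frames)",
                  dt[i], dtS, df[i]))
      gap <- which(df > 1L)
      for (i in gap)
        out[[length(out) + 1L]] <- finding(
          id, p$frame[i + 1L], "info",
          sprintf("gap of %d missing frame(s) before frame %d",
                  df[i] - 1L, p$frame[i + 1L]))
    }
    coords <- as.matrix(p[, c("x_um", "y_um", "z_um")])
    if (nrow(p) && !all(is.finite(coords)))
      out[[length(out) + 1L]] <- finding(
        id, p$frame[which(!stats::complete.cases(coords) |
                            rowSums(!is.finite(coords)) > 0)[1L]],
        "error", "non-finite coordinate")
    if (nrow(p) && any(!is.finite(p$time_s) | p$time_s < 0))
      out[[length(out) + 1L]] <- finding(
        id, p$frame[which(!is.finite(p$time_s) | p$time_s < 0)[1L]],
        "error", "time_s must be finite and non-negative")
  }
  if (!length(out))
    return(data.frame(cell_id = character(), frame = integer(),
                      severity = character(), message = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
})
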
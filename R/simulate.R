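#' @include AllClasses.R AllGenerics.R detection.R
NULL

.rowNorm <- function(m) sqrt(rowSums(m * m))

.unitRows <- function(m) {
  n <- .rowNorm(m)
  n[n < 1e-12] <- 1
  m / n
}

.randUnit <- function(n) .unitRows(matrix(stats::rnorm(n * 3L), n, 3L))

## one unit vector perpendicular to u (plus a random azimuth)
.perpUnit <- function(u) {
  a <- stats::rnorm(3L)
  p <- a - sum(a * u) / sum(u * u) * u
  if (sqrt(sum(p * p)) < 1e-9) p <- c(-u[2L], u[1L], 0)
  p / sqrt(sum(p * p))
}

.fovSeed <- function(seed, fovIndex)
  as.integer((as.numeric(seed) * 7919 + as.numeric(fovIndex) * 104729) %%
               2147483629)

#' Simulate one field of view with planted contact episodes
#'
#' Generates a synthetic two-photon-like movie: NK (and T) cells follow 3D
#' persistent random walks with per-frame speeds drawn around a per-track
#' mean; dendritic cells wobble slowly around fixed anchors
#' (mean-reverting); boundaries are reflective. For each planted episode
#' the NK cell is steered onto its DC in phases: a straight fast approach
#' (scheduled so the cell reaches the dwell sphere one frame before the
#' episode), a fast holding orbit if it arrives early, then a slow dwell in
#' which each step moves toward the cell's own track origin (so the
#' confinement ratio is non-increasing) while staying within the dwell
#' distance of the DC, and finally a fast radial departure. Approach,
#' orbit and departure steps run at 1.2x the nominal NK speed, so the
#' frames flanking an episode always fail the speed criterion and a
#' noiseless planted k-frame episode is detected with exactly k frames.
#'
#' Localization jitter and frame drops configured in the
#' [SimulationConfig-class] are applied through [addNoise()] after the
#' dynamics, so noise never feeds back into the motion. A fixed
#' (`seed`, `fovIndex`) pair reproduces the output bit-identically.
#'
#' @param config a [SimulationConfig-class].
#' @param fovIndex integer(1); each index yields an independent,
#'   reproducible random stream.
#' @return list with `fov` (a [FieldOfView-class]) and `truth` (data.frame
#'   of planted episodes: `fov_id`, `nk_id`, `dc_id`, `start_frame`,
#'   `n_frames`, `duration_s`, `class`).
#' @seealso [addNoise()], [recoveryExperiment()]
#' @export
simulateFov <- function(config, fovIndex = 1L) {
  validObject(config)
  set.seed(.fovSeed(config@seed, fovIndex))
  nF <- config@nFrames
  dtS <- config@frameIntervalS
  dtMin <- dtS / 60
  vol <- config@volumeUm
  nNk <- config@nNk; nDc <- config@nDc; nT <- config@nT
  nkIds <- sprintf("NK%03d", seq_len(nNk))
  dcIds <- sprintf("DC%03d", seq_len(nDc))
  tIds <- sprintf("T%03d", seq_len(nT))
  ep <- config@episodes

  ## --- dendritic cells: anchors + mean-reverting wobble ---------------
  margin <- pmin(30, vol / 4)
  anchor <- matrix(0, max(nDc, 1L), 3L)
  if (nDc) {
    for (k in 1:3) anchor[, k] <- stats::runif(nDc, margin[k], vol[k] - margin[k])
    if (config@dcSeparationUm > 0)
      anchor[, 1L] <- vol[1L] + config@dcSeparationUm +
        stats::runif(nDc, 0, 40)
  }
  dcSd <- config@dcDriftUmMin * dtMin / 1.6   # mean step ~ drift * dt
  dcX <- array(0, c(nF, max(nDc, 1L), 3L))
  if (nDc) {
    dcX[1L, , ] <- anchor
    for (f in 2:nF) {
      prev <- matrix(dcX[f - 1L, , ], nDc, 3L)
      dcX[f, , ] <- anchor + 0.85 * (prev - anchor) +
        matrix(stats::rnorm(nDc * 3L, sd = dcSd), nDc, 3L)
    }
  }

  ## --- motile cells (NK then T) ---------------------------------------
  nM <- nNk + nT
  ids <- c(nkIds, tIds)
  vMean <- c(pmax(1, stats::rnorm(nNk, config@nkSpeedMeanUmMin,
                                  config@nkSpeedSdUmMin)),
             pmax(1, stats::rnorm(nT, config@tSpeedMeanUmMin,
                                  config@tSpeedSdUmMin)))
  withinSd <- c(rep(config@nkSpeedWithinSdUmMin, nNk),
                rep(config@nkSpeedWithinSdUmMin, nT))
  pos <- matrix(stats::runif(nM * 3L), nM, 3L) %*% diag(vol)
  H <- .randUnit(max(nM, 1L))

  appStep <- 1.2 * config@nkSpeedMeanUmMin * dtMin

  ## planted cells start within reach of their first DC, scaled to what the
  ## approach can cover before the episode, so docking is never a jump
  epIdx <- if (nrow(ep))
    lapply(split(seq_len(nrow(ep)), ep$nk_id),
           function(ii) ii[order(ep$start_frame[ii])])
  else list()
  curPtr <- stats::setNames(rep(1L, length(epIdx)), names(epIdx))
  planted <- which(ids %in% names(epIdx))
  for (j in planted) {
    e <- ep[epIdx[[ids[j]]][1L], ]
    dcA <- anchor[match(e$dc_id, dcIds), ]
    hi <- min(60, e$dwell_dist_um + appStep * max(3, e$start_frame - 8L))
    lo <- min(20, 0.5 * hi)
    p <- dcA + stats::runif(1, lo, hi) * as.vector(.randUnit(1L))
    pos[j, ] <- pmin(pmax(p, 1), vol - 1)
  }
  stage <- rep("prw", nM)
  uDep <- matrix(0, nM, 3L)

  X <- array(NA_real_, c(nF, max(nM, 1L), 3L))
  if (nM) X[1L, , ] <- pos
  kap <- config@persistence

  orbitStep <- function(p, dcP, rArr) {
    u <- p - dcP
    r <- sqrt(sum(u * u))
    if (r < 1e-9) { u <- as.vector(.randUnit(1L)); r <- 1 }
    tang <- .perpUnit(u / r)
    raw <- p + appStep * tang
    w <- raw - dcP
    dcP + rArr * w / sqrt(sum(w * w))
  }

  if (nM) for (f in 2:nF) {
    v <- pmax(0.05, stats::rnorm(nM, vMean, withinSd))
    H <- .unitRows(kap * H + (1 - kap) * .randUnit(nM))
    disp <- H * (v * dtMin)

    for (j in planted) {
      rows <- epIdx[[ids[j]]]
      if (curPtr[ids[j]] > length(rows)) next
      e <- ep[rows[curPtr[ids[j]]], ]
      s <- e$start_frame + 1L          # 1-based frame row
      en <- s + e$n_frames - 1L
      rArr <- e$dwell_dist_um
      clampRad <- rArr + 5
      dcP <- dcX[f, match(e$dc_id, dcIds), ]
      p <- pos[j, ]
      if (f < s) {
        if (stage[j] == "prw") {
          distDc <- sqrt(sum((p - dcP)^2))
          need <- ceiling(max(0, distDc - rArr) / appStep)
          if ((s - 1L - f) <= need + 2L) stage[j] <- "approach"
        }
        if (stage[j] == "approach" &&
            sqrt(sum((p - dcP)^2)) <= rArr) stage[j] <- "hold"
        if (f == s - 1L) {
          disp[j, ] <- orbitStep(p, dcP, rArr) - p   # dock on the sphere, fast
          stage[j] <- "dwell"
        } else if (stage[j] == "approach") {
          disp[j, ] <- appStep * (dcP - p) / sqrt(sum((dcP - p)^2))
        } else if (stage[j] == "hold") {
          disp[j, ] <- orbitStep(p, dcP, rArr) - p
        }
      } else if (f >= s && f <= en) {
        org <- X[1L, j, ]
        u <- org - p
        dstep <- e$dwell_speed_frac * config@nkSpeedMeanUmMin * dtMin
        prop <- if (sqrt(sum(u * u)) <= dstep) org
                else p + dstep * u / sqrt(sum(u * u))
        if (sqrt(sum((prop - dcP)^2)) > clampRad) prop <- p
        disp[j, ] <- prop - p
      } else if (f > en && f <= en + 3L) {
        if (f == en + 1L) {
          w <- p - dcP
          nw <- sqrt(sum(w * w))
          uDep[j, ] <- if (nw < 1e-9) as.vector(.randUnit(1L)) else w / nw
          stage[j] <- "depart"
        }
        disp[j, ] <- appStep * uDep[j, ]
      } else if (f == en + 4L) {
        stage[j] <- "prw"
        H[j, ] <- uDep[j, ]
        curPtr[ids[j]] <- curPtr[ids[j]] + 1L
      }
    }

    pos <- pos + disp
    for (k in 1:3) {          # reflective boundaries (position and heading)
      under <- pos[, k] < 0
      pos[under, k] <- -pos[under, k]
      over <- pos[, k] > vol[k]
      pos[over, k] <- 2 * vol[k] - pos[over, k]
      H[under | over, k] <- -H[under | over, k]
    }
    X[f, , ] <- pos
  }

  ## --- assemble -------------------------------------------------------
  fid <- sprintf("sim%03d", fovIndex)
  frames <- 0:(nF - 1L)
  times <- frames * dtS
  trjs <- vector("list", nM + nDc)
  if (nM) for (j in seq_len(nM))
    trjs[[j]] <- Trajectory(ids[j], if (j <= nNk) "NK" else "T", frames,
                            X[, j, 1L], X[, j, 2L], X[, j, 3L], timeS = times)
  if (nDc) for (k in seq_len(nDc))
    trjs[[nM + k]] <- Trajectory(dcIds[k], "DC", frames, dcX[, k, 1L],
                                 dcX[, k, 2L], dcX[, k, 3L], timeS = times)
  fov <- FieldOfView(fid, trjs, condition = config@condition,
                     frameIntervalS = dtS)
  if (config@jitterSdUm > 0 || config@dropP > 0)
    fov <- addNoise(fov, jitterSdUm = config@jitterSdUm,
                    dropP = config@dropP,
                    seed = .fovSeed(config@seed + 1L, fovIndex))
  truth <- if (nrow(ep))
    data.frame(fov_id = fid, nk_id = ep$nk_id, dc_id = ep$dc_id,
               start_frame = ep$start_frame, n_frames = ep$n_frames,
               duration_s = ep$n_frames * dtS,
               class = classifyEvent(ep$n_frames * dtS))
  else
    data.frame(fov_id = character(), nk_id = character(),
               dc_id = character(), start_frame = integer(),
               n_frames = integer(), duration_s = numeric(),
               class = character())
  list(fov = fov, truth = truth)
}

#' Add localization noise and frame drops to a field of view
#'
#' Applies i.i.d. Gaussian displacement (sd `jitterSdUm` per coordinate,
#' per point) and drops frames independently per cell per frame with
#' probability `dropP`. Deterministic under `seed`. Tracks reduced below 2
#' points are kept (so [validateFov()] can report them) rather than raised.
#'
#' @param fov a [FieldOfView-class].
#' @param jitterSdUm jitter sd in micrometres (>= 0).
#' @param dropP drop probability in \[0, 1).
#' @param seed integer seed.
#' @return A new [FieldOfView-class].
#' @export
addNoise <- function(fov, jitterSdUm = 0, dropP = 0, seed = 1L) {
  stopifnot(jitterSdUm >= 0, dropP >= 0, dropP < 1)
  if (jitterSdUm == 0 && dropP == 0) return(fov)
  set.seed(as.integer(seed) %% 2147483629L)
  trjs <- lapply(fov@trajectories, function(t) {
    p <- t@points
    n <- nrow(p)
    keep <- if (dropP > 0) stats::runif(n) >= dropP else rep(TRUE, n)
    if (!any(keep)) keep[sample.int(n, 1L)] <- TRUE   # keep tracks non-empty
    p <- p[keep, , drop = FALSE]
    if (jitterSdUm > 0) {
      m <- nrow(p)
      p$x_um <- p$x_um + stats::rnorm(m, sd = jitterSdUm)
      p$y_um <- p$y_um + stats::rnorm(m, sd = jitterSdUm)
      p$z_um <- p$z_um + stats::rnorm(m, sd = jitterSdUm)
    }
    rownames(p) <- NULL
    methods::initialize(t, points = p)
  })
  methods::initialize(fov, trajectories = trjs)
}

#' Build a recovery-experiment configuration
#'
#' Convenience constructor for parameter-recovery studies: plants one
#' contact episode on a chosen fraction of the NK cells, a chosen fraction
#' of which are long (>= the long threshold; 40 frames at the default 30 s
#' interval, i.e. 1200 s), the rest intermediate (5-15 frames). Dwell
#' parameters sit strictly inside the default detector thresholds
#' (dwell distance 12.5 um = d/2, dwell speed fraction 0.15 of the nominal
#' NK speed).
#'
#' @param plantFraction fraction of NK cells given an episode, in \[0, 1\].
#' @param longFraction fraction of planted episodes that are long.
#' @param nNk,nDc cells per field of view.
#' @param nFrames,frameIntervalS movie geometry.
#' @param seed integer seed (also used to sample the episode table).
#' @param jitterSdUm,dropP noise settings passed into the config.
#' @param condition condition label.
#' @return A [SimulationConfig-class].
#' @export
makeRecoveryConfig <- function(plantFraction, longFraction = 0, nNk = 100L,
                               nDc = 8L, nFrames = 120L, frameIntervalS = 30,
                               seed = 1L, jitterSdUm = 0, dropP = 0,
                               condition = "steady_state") {
  stopifnot(plantFraction >= 0, plantFraction <= 1,
            longFraction >= 0, longFraction <= 1)
  set.seed(.fovSeed(seed, 0L))
  nkIds <- sprintf("NK%03d", seq_len(nNk))
  dcIds <- sprintf("DC%03d", seq_len(nDc))
  nPlant <- round(plantFraction * nNk)
  longFrames <- ceiling(1200 / frameIntervalS)
  episodes <- NULL
  if (nPlant > 0) {
    planted <- sample(nkIds, nPlant)
    nLong <- round(longFraction * nPlant)
    isLong <- seq_len(nPlant) <= nLong
    nfr <- ifelse(isLong, longFrames,
                  sample(5:15, nPlant, replace = TRUE))
    lead <- 25L   # frames reserved for the scheduled approach
    start <- vapply(nfr, function(n) {
      hi <- nFrames - n - 5L
      if (hi <= lead) lead else sample(lead:hi, 1L)
    }, integer(1))
    episodes <- data.frame(nk_id = planted,
                           dc_id = sample(dcIds, nPlant, replace = TRUE),
                           start_frame = start, n_frames = as.integer(nfr),
                           dwell_dist_um = 12.5, dwell_speed_frac = 0.15)
  }
  SimulationConfig(seed = seed, nFrames = nFrames,
                   frameIntervalS = frameIntervalS, nNk = nNk, nDc = nDc,
                   jitterSdUm = jitterSdUm, dropP = dropP,
                   episodes = episodes, condition = condition)
}

#' Build a null (no-contact) configuration
#'
#' NK cells and dendritic cells confined to volumes separated by at least
#' `separationUm` (default 2 x 25 um), with no planted episodes: a
#' specificity control in which the detector must return no events.
#'
#' @param seed integer seed.
#' @param nNk,nDc cells per field of view.
#' @param separationUm enforced minimum NK-DC distance.
#' @return A [SimulationConfig-class].
#' @export
makeNullConfig <- function(seed = 1L, nNk = 20L, nDc = 5L,
                           separationUm = 50) {
  SimulationConfig(seed = seed, nNk = nNk, nDc = nDc,
                   dcSeparationUm = separationUm)
}

#' Planted-versus-recovered validation experiment
#'
#' Runs `nReps` independent simulations of one configuration, detects
#' events in each, and compares recovered against planted quantities:
#' the interacting fraction, the long fraction among interacting cells,
#' and per-episode duration errors in frames (each planted episode is
#' matched to the detected event of its NK-DC pair with maximal frame
#' overlap; unmatched episodes count their full length as error).
#'
#' @param config a [SimulationConfig-class] (typically from
#'   [makeRecoveryConfig()]).
#' @param detector a [DetectorConfig-class].
#' @param nReps number of replicate fields of view.
#' @return list with `reps` (one row per replicate: planted and recovered
#'   fractions), `episodes` (one row per planted episode per replicate:
#'   matched flag and duration error in frames), and `summary` (means +/-
#'   SEM of the recovered fractions and the median absolute duration
#'   error).
#' @export
recoveryExperiment <- function(config, detector = DetectorConfig(),
                               nReps = 20L) {
  reps <- vector("list", nReps)
  eps <- vector("list", nReps)
  for (r in seq_len(nReps)) {
    sim <- simulateFov(config, fovIndex = r)
    fov <- sim$fov
    truth <- sim$truth
    events <- detectAll(fov, detector)
    nNk <- length(cellIds(fov, "NK"))
    plantedIds <- unique(truth$nk_id)
    lf <- longFraction(events)
    plantedLong <- if (nrow(truth)) {
      perCell <- vapply(split(truth, truth$nk_id), function(e)
        any(e$class == "long"), logical(1))
      100 * sum(perCell) / length(perCell)
    } else 0
    reps[[r]] <- data.frame(
      rep = r,
      planted_fraction_pct = 100 * length(plantedIds) / nNk,
      recovered_fraction_pct = interactingFraction(events, fov),
      planted_long_pct = plantedLong,
      recovered_long_pct = as.numeric(lf),
      n_events = nrow(events))
    if (nrow(truth)) {
      err <- vapply(seq_len(nrow(truth)), function(i) {
        tr <- truth[i, ]
        ev <- events[events$nk_id == tr$nk_id & events$dc_id == tr$dc_id, ,
                     drop = FALSE]
        if (!nrow(ev)) return(NA_integer_)
        ov <- pmax(0L, pmin(ev$end_frame, tr$start_frame + tr$n_frames - 1L) -
                     pmax(ev$start_frame, tr$start_frame) + 1L)
        if (max(ov) == 0L) return(NA_integer_)
        ev$n_frames[which.max(ov)]
      }, integer(1))
      eps[[r]] <- data.frame(rep = r, nk_id = truth$nk_id,
                             dc_id = truth$dc_id,
                             planted_frames = truth$n_frames,
                             detected_frames = err,
                             matched = !is.na(err),
                             err_frames = ifelse(is.na(err), truth$n_frames,
                                                 abs(err - truth$n_frames)))
    }
  }
  reps <- do.call(rbind, reps)
  episodes <- if (length(Filter(Negate(is.null), eps)))
    do.call(rbind, eps)
  else data.frame(rep = integer(), nk_id = character(), dc_id = character(),
                  planted_frames = integer(), detected_frames = integer(),
                  matched = logical(), err_frames = numeric())
  sem <- function(x) if (length(x) >= 2L) stats::sd(x) / sqrt(length(x)) else NA_real_
  list(reps = reps, episodes = episodes,
       summary = list(
         planted_fraction_pct = mean(reps$planted_fraction_pct),
         recovered_fraction_mean_pct = mean(reps$recovered_fraction_pct),
         recovered_fraction_sem_pct = sem(reps$recovered_fraction_pct),
         planted_long_pct = mean(reps$planted_long_pct),
         recovered_long_mean_pct = mean(reps$recovered_long_pct),
         recovered_long_sem_pct = sem(reps$recovered_long_pct),
         median_abs_duration_err_frames =
           if (nrow(episodes)) stats::median(episodes$err_frames) else NA_real_))
}
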
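# Fixture builders and independent oracle implementations used across the
# suite. Oracles are deliberately written in a different style from the
# package code (explicit loops, no shared helpers) so they check, rather
# than mirror, the implementation.

makeTrack <- function(id = "NK1", type = "NK", x, y = 0, z = 0,
                      dtS = 30, frames = NULL) {
  n <- length(x)
  if (is.null(frames)) frames <- 0:(n - 1L)
  Trajectory(id, type, frames, x = x, y = rep_len(y, n), z = rep_len(z, n),
             timeS = frames * dtS)
}

randomTrack <- function(id = "NK1", type = "NK", n = 50, dtS = 30,
                        stepSd = 3) {
  steps <- matrix(rnorm(3 * (n - 1), sd = stepSd), n - 1, 3)
  xyz <- apply(rbind(runif(3, 0, 100), steps), 2, cumsum)
  makeTrack(id, type, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], dtS = dtS)
}

# finite-difference speed oracle (um/min), frame 0 copying frame 1
oracleSpeeds <- function(track) {
  p <- trackPoints(track)
  v <- numeric(nrow(p))
  for (i in 2:nrow(p)) {
    d <- sqrt((p$x_um[i] - p$x_um[i - 1])^2 + (p$y_um[i] - p$y_um[i - 1])^2 +
                (p$z_um[i] - p$z_um[i - 1])^2)
    v[i] <- d / (p$time_s[i] - p$time_s[i - 1]) * 60
  }
  v[1] <- v[2]
  v
}

# run-merging oracle for the tolerance semantics: find maximal all-three
# runs, then repeatedly merge runs separated by exactly one frame failing
# exactly one criterion
oracleRuns <- function(met, tolerance = TRUE) {
  n <- nrow(met)
  all3 <- rowSums(met) == 3
  runs <- list()
  i <- 1
  while (i <= n) {
    if (all3[i]) {
      j <- i
      while (j < n && all3[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j, 0)
      i <- j + 1
    } else i <- i + 1
  }
  if (!length(runs)) return(NULL)
  if (tolerance) {
    repeat {
      merged <- FALSE
      k <- 1
      while (k < length(runs)) {
        a <- runs[[k]]; b <- runs[[k + 1]]
        gap <- b[1] - a[2] - 1
        if (gap == 1 && sum(met[a[2] + 1, ]) == 2) {
          runs[[k]] <- c(a[1], b[2], a[3] + b[3] + 1)
          runs[[k + 1]] <- NULL
          merged <- TRUE
        } else k <- k + 1
      }
      if (!merged) break
    }
  }
  out <- do.call(rbind, runs)
  data.frame(i0 = out[, 1], i1 = out[, 2], n_tol = out[, 3])
}

randomCriteria <- function(n, p = c(0.6, 0.6, 0.6)) {
  cbind(runif(n) < p[1], runif(n) < p[2], runif(n) < p[3])
}

# textbook equal-variance two-sample t statistic and two-sided p
oracleTTest <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# binomial 95% interval for a recovered count at n cells, on the percent scale
binomIntervalPct <- function(p, n)
  100 * qbinom(c(0.025, 0.975), n, p) / n
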
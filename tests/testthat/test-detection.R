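test_that("pair distance: 3-4-5 triangle, identical positions, disjoint frames", {
  nk <- makeTrack("NK1", x = c(0, 0))
  dc <- makeTrack("DC1", type = "DC", x = c(3, 3), y = c(4, 4))
  pd <- pairDistance(nk, dc)
  expect_equal(pd$dist_um, c(5, 5))
  expect_true(all(pd$dist_met))
  expect_equal(pd$dist_d, c(-0.15, -0.15))

  same <- pairDistance(nk, makeTrack("DC2", type = "DC", x = c(0, 0)))
  expect_equal(same$dist_um, c(0, 0))

  far <- pairDistance(nk, makeTrack("DC3", type = "DC", x = c(40, 40)))
  expect_false(any(far$dist_met))
  expect_equal(far$dist_d, c(0, 0))

  disjoint <- pairDistance(nk, makeTrack("DC4", type = "DC", x = c(0, 0),
                                         frames = c(10, 11)))
  expect_identical(nrow(disjoint), 0L)

  set.seed(5)
  a <- randomTrack("NK1", n = 40); b <- randomTrack("DC1", "DC", n = 40)
  pa <- trackPoints(a); pb <- trackPoints(b)
  pd <- pairDistance(a, b)
  for (i in seq_len(nrow(pd))) {
    j <- match(pd$frame[i], pa$frame); k <- match(pd$frame[i], pb$frame)
    expect_equal(pd$dist_um[i],
                 sqrt((pa$x_um[j] - pb$x_um[k])^2 + (pa$y_um[j] - pb$y_um[k])^2 +
                        (pa$z_um[j] - pb$z_um[k])^2),
                 tolerance = 1e-12)
  }
})

test_that("confinement criterion: constant-or-decreasing with tolerance, first frame FALSE", {
  expect_equal(confinementCriterion(c(1.0, 0.9, 0.8)), c(FALSE, TRUE, TRUE))
  expect_equal(confinementCriterion(c(0.5, 0.6)), c(FALSE, FALSE))
  eps <- 0.01
  expect_equal(confinementCriterion(c(0.5, 0.5 + eps / 2), eps),
               c(FALSE, TRUE))
  expect_equal(confinementCriterion(c(0.5, 0.5)), c(FALSE, TRUE))
})

test_that("speed criterion boundary is inclusive at alpha * V_FOV", {
  expect_true(speedCriterion(6.0, 10, 0.6))
  expect_false(speedCriterion(6.0001, 10, 0.6))
  expect_true(speedCriterion(0, 10, 0.6))
  expect_error(speedCriterion(5, -1), "positive")
})

test_that("tolerance absorbs an isolated single-criterion failure but never two in a row", {
  # frames 3-10 all qualify except frame 6, where only the speed criterion fails
  m <- matrix(TRUE, 8, 3)
  m[4, 2] <- FALSE
  runs <- segmentQualifyingRuns(m, tolerance = TRUE)
  expect_equal(unlist(runs), c(i0 = 1, i1 = 8, n_tol = 1),
               ignore_attr = FALSE)
  # without tolerance the run splits
  expect_equal(segmentQualifyingRuns(m, tolerance = FALSE)$i0, c(1, 5))

  # frames 6 AND 7 failing -> two events
  m2 <- matrix(TRUE, 8, 3)
  m2[4:5, 2] <- FALSE
  runs2 <- segmentQualifyingRuns(m2)
  expect_equal(runs2$i0, c(1, 6))
  expect_equal(runs2$i1, c(3, 8))
  expect_equal(runs2$n_tol, c(0, 0))

  # a frame failing TWO criteria is never absorbed
  m3 <- matrix(TRUE, 8, 3)
  m3[4, 2:3] <- FALSE
  expect_equal(segmentQualifyingRuns(m3)$i0, c(1, 5))

  # edge frames are not absorbable
  m4 <- matrix(TRUE, 5, 3)
  m4[1, 1] <- FALSE; m4[5, 3] <- FALSE
  expect_equal(unname(unlist(segmentQualifyingRuns(m4))), c(2, 4, 0))

  expect_null(segmentQualifyingRuns(matrix(FALSE, 6, 3)))
})

test_that("segmentation agrees with the run-merging oracle on random criterion sequences", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    m <- randomCriteria(n, p = runif(3, 0.3, 0.9))
    tol <- i %% 2 == 0
    got <- segmentQualifyingRuns(m, tolerance = tol)
    want <- oracleRuns(m, tolerance = tol)
    if (is.null(want)) expect_null(got)
    else expect_equal(as.data.frame(got), want, ignore_attr = TRUE)
  }
})

test_that("tolerance is monotone: events only grow and qualifying frames never decrease", {
  set.seed(99)
  for (i in 1:200) {
    m <- randomCriteria(sample(5:30, 1), p = runif(3, 0.4, 0.95))
    off <- segmentQualifyingRuns(m, tolerance = FALSE)
    on <- segmentQualifyingRuns(m, tolerance = TRUE)
    if (is.null(off)) next
    expect_false(is.null(on))
    framesOff <- sum(off$i1 - off$i0 + 1)
    framesOn <- sum(on$i1 - on$i0 + 1)
    expect_gte(framesOn, framesOff)
    for (k in seq_len(nrow(off))) # every tolerance-off event is contained in one
      expect_true(any(on$i0 <= off$i0[k] & on$i1 >= off$i1[k]))
    for (k in seq_len(nrow(on))) { # every event frame meets 3 criteria or is absorbed with 2
      counts <- rowSums(m[on$i0[k]:on$i1[k], , drop = FALSE])
      expect_true(all(counts >= 2))
      expect_equal(sum(counts == 2), on$n_tol[k])
    }
  }
})

test_that("detectEvents finds the engineered slow-near-DC window on constructed tracks", {
  # NK walks straight toward a static DC at the origin: fast (15 um/frame)
  # until 25 um away, slow (2 um/frame) for 8 frames, then fast again
  x <- c(100, 85, 70, 55, 40, 25, 23, 21, 19, 17, 15, 13, 11, 9, -6, -21, -36)
  nk <- makeTrack("NK1", x = x)
  dc <- makeTrack("DC1", type = "DC", x = rep(0, length(x)))
  ev <- detectEvents(nk, dc, vFov = 10, config = DetectorConfig(),
                     frameIntervalS = 30)
  expect_identical(nrow(ev), 1L)
  expect_equal(ev$start_frame, 6)
  expect_equal(ev$end_frame, 13)
  expect_equal(ev$n_frames, 8L)
  expect_equal(ev$duration_s, 240)
  expect_equal(ev$class, "intermediate")
  expect_equal(ev$n_tolerated_frames, 0L)

  # the distance-only baseline over-calls: it also counts the fast frames within d
  base <- distanceOnlyEvents(nk, dc, d = 25, frameIntervalS = 30)
  expect_identical(nrow(base$events), 1L)
  expect_equal(base$events$start_frame, 5)
  expect_equal(base$events$end_frame, 15)
  expect_gt(base$events$n_frames, ev$n_frames)
  expect_equal(base$series$t_on_off[base$series$on], rep(-1, 11))
})

test_that("a high-speed pass-by within d is called by the baseline but not the detector", {
  # NK crosses within 5 um of the DC at 30 um/min and never slows
  x <- seq(-60, 60, by = 15)
  nk <- makeTrack("NK1", x = x, y = 5)
  dc <- makeTrack("DC1", type = "DC", x = rep(0, length(x)))
  expect_identical(nrow(detectEvents(nk, dc, vFov = 10)), 0L)
  expect_gte(nrow(distanceOnlyEvents(nk, dc)$events), 1L)
  expect_identical(nrow(distanceOnlyEvents(
    makeTrack("NK1", x = c(100, 101)), dc)$events), 0L)
})

test_that("gaps in shared frames always break runs", {
  # identical geometry, but the DC track misses frame 9 (interior slow frame)
  x <- c(100, 85, 70, 55, 40, 25, 23, 21, 19, 17, 15, 13, 11, 9, -6, -21)
  nk <- makeTrack("NK1", x = x)
  dcFrames <- setdiff(0:(length(x) - 1), 9)
  dc <- makeTrack("DC1", type = "DC", x = rep(0, length(dcFrames)),
                  frames = dcFrames)
  ev <- detectEvents(nk, dc, vFov = 10)
  expect_identical(nrow(ev), 2L)
  expect_equal(ev$start_frame, c(6, 10))
  expect_equal(ev$end_frame, c(8, 13))
})

test_that("event classification thresholds match the printed operating point", {
  cfg <- DetectorConfig()
  expect_equal(classifyEvent(c(930, 4, 300, 900, 899, 5), cfg),
               c("long", "touch_and_go", "intermediate", "long",
                 "intermediate", "intermediate"))
})

test_that("detectAll is gate-invariant, order-invariant and respects cell-type contracts", {
  set.seed(21)
  cfg <- makeRecoveryConfig(plantFraction = 0.4, nNk = 10, nDc = 4, seed = 77)
  fov <- simulateFov(cfg)$fov
  evGate <- detectAll(fov, gate = TRUE)
  evAll <- detectAll(fov, gate = FALSE)
  expect_equal(evGate, evAll)

  shuffled <- FieldOfView(fovId(fov), rev(unname(trajectories(fov))),
                          condition = condition(fov),
                          frameIntervalS = frameInterval(fov))
  expect_equal(detectAll(shuffled), evGate)

  onlyNk <- FieldOfView("f", list(makeTrack("NK1", x = c(0, 5, 10))))
  expect_error(detectAll(onlyNk), "no DC")
  onlyDc <- FieldOfView("f", list(makeTrack("DC1", type = "DC", x = 0:2)))
  expect_error(detectAll(onlyDc), "no NK")
})

test_that("enlarging d or alpha never decreases total event frames", {
  set.seed(31)
  cfg <- makeRecoveryConfig(plantFraction = 0.5, nNk = 8, nDc = 3, seed = 5,
                            jitterSdUm = 0.5)
  fov <- simulateFov(cfg)$fov
  total <- function(d, a) {
    ev <- detectAll(fov, DetectorConfig(distanceThresholdUm = d,
                                        speedFraction = a))
    sum(ev$n_frames)
  }
  base <- total(25, 0.6)
  expect_gte(total(30, 0.6), base)
  expect_gte(total(25, 0.7), base)
  expect_gte(total(35, 0.8), total(30, 0.7))
})
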
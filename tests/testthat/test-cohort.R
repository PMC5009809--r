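fakeEvents <- function(nkIds, durations, fovIds = "f",
                       dcIds = "DC1", config = DetectorConfig()) {
  n <- length(nkIds)
  if (n == 0L) durations <- numeric(0)
  data.frame(fov_id = rep_len(fovIds, n),
             condition = rep_len("steady_state", n),
             nk_id = nkIds, dc_id = rep_len(dcIds, n),
             start_frame = rep_len(0L, n), end_frame = rep_len(0L, n),
             n_frames = rep_len(1L, n), n_tolerated_frames = rep_len(0L, n),
             duration_s = rep_len(durations, n),
             class = as.character(classifyEvent(rep_len(durations, n), config)))
}

nkFov <- function(n, fovId = "f") {
  FieldOfView(fovId, lapply(seq_len(n), function(i)
    makeTrack(sprintf("NK%02d", i), x = c(0, 5, 10))))
}

test_that("interacting fraction is the percent of NK tracks with at least one event", {
  fov <- nkFov(20)
  ev <- fakeEvents(sprintf("NK%02d", 1:9), 300)
  expect_equal(interactingFraction(ev, fov), 45)
  expect_equal(interactingFraction(fakeEvents(character(0), numeric(0)), fov), 0)
  evAll <- fakeEvents(sprintf("NK%02d", 1:20), 300)
  expect_equal(interactingFraction(evAll, fov), 100)
  # splitting a cell's events across DCs changes nothing
  evSplit <- rbind(ev, fakeEvents(sprintf("NK%02d", 1:9), 60, dcIds = "DC2"))
  expect_equal(interactingFraction(evSplit, fov), 45)
  expect_equal(interactingFraction(evSplit[sample(nrow(evSplit)), ], fov), 45)
  # adding a non-interacting track decreases it; an extra event does not
  expect_lt(interactingFraction(ev, nkFov(21)), 45)
  expect_error(interactingFraction(ev, FieldOfView("g", list())), "no NK")
})

test_that("long fraction is per cell, judged on the longest event", {
  ids <- sprintf("NK%02d", 1:50)
  ev <- fakeEvents(ids, 300)
  evLong <- rbind(ev, fakeEvents(ids[1:6], 1200))
  lf <- longFraction(evLong)
  expect_equal(as.numeric(lf), 12)
  expect_equal(attr(lf, "n_interacting"), 50L)
  expect_equal(attr(lf, "n_long"), 6L)
  expect_equal(as.numeric(longFraction(ev)), 0)
  expect_equal(as.numeric(longFraction(fakeEvents(ids, 1000))), 100)
  empty <- longFraction(fakeEvents(character(0), numeric(0)))
  expect_equal(as.numeric(empty), 0)
  expect_true(attr(empty, "no_interacting"))
  # a long event does not leak across cells keyed by fov_id
  twoFov <- rbind(fakeEvents("NK01", 1200, fovIds = "a"),
                  fakeEvents("NK01", 100, fovIds = "b"))
  expect_equal(attr(longFraction(twoFov), "n_interacting"), 2L)
  expect_equal(attr(longFraction(twoFov), "n_long"), 1L)
})

test_that("duration summary gives mean, SEM and class counts", {
  ev <- fakeEvents(c("a", "b", "c"), c(100, 200, 300))
  ds <- durationSummary(ev)
  expect_equal(ds$mean_s, 200)
  expect_equal(ds$sem_s, 57.735, tolerance = 1e-4)
  expect_equal(unname(ds$class_counts["intermediate"]), 3L)

  one <- durationSummary(fakeEvents("a", 50))
  expect_true(is.na(one$sem_s))
  expect_equal(durationSummary(fakeEvents(character(0), numeric(0)))$n, 0L)

  set.seed(13)
  d <- runif(30, 10, 2000)
  ds2 <- durationSummary(fakeEvents(sprintf("c%d", 1:30), d))
  expect_equal(ds2$mean_s, mean(d))
  expect_equal(ds2$sem_s, sd(d) / sqrt(30))
})

test_that("velocity summary returns per-cell mean speeds for interacting cells", {
  nk1 <- makeTrack("NK1", x = seq(0, 20, by = 4))    # 8 um/min
  nk2 <- makeTrack("NK2", x = seq(0, 30, by = 6))    # 12 um/min
  fov <- FieldOfView("f", list(nk1, nk2), condition = "LPS")
  vs <- velocitySummary(fov, c("NK1", "NK2"))
  expect_equal(sort(vs$v_mean_um_min), c(8, 12))
  expect_equal(mean(vs$v_mean_um_min), 10)
  expect_equal(unique(vs$condition), "LPS")
  expect_identical(nrow(velocitySummary(fov, character(0))), 0L)
  expect_error(velocitySummary(fov, "NK9"), "unknown NK cell id")
})

test_that("condition comparison is an unpaired two-tailed equal-variance t-test", {
  same <- compareConditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$zero_variance)

  degen <- compareConditions(c(0, 0, 0, 0), c(1, 1, 1, 1))
  expect_true(degen$zero_variance)
  expect_true(is.na(degen$p))

  set.seed(8)
  for (i in 1:10) {
    a <- rnorm(sample(3:20, 1)); b <- rnorm(sample(3:20, 1), mean = runif(1))
    got <- compareConditions(a, b)
    want <- oracleTTest(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$p, want$p, tolerance = 1e-12)
    flipped <- compareConditions(b, a)
    expect_equal(flipped$t, -got$t, tolerance = 1e-12)
    expect_equal(flipped$p, got$p, tolerance = 1e-12)
    expect_true(got$p >= 0 && got$p <= 1)
    expect_equal(got$sem_a, sd(a) / sqrt(length(a)))
  }
  expect_error(compareConditions(1, c(1, 2)), "at least 2")
})

test_that("cohort summary aggregates per condition with both long-fraction denominators", {
  set.seed(17)
  cfgA <- makeRecoveryConfig(0.5, longFraction = 0.5, nNk = 8, nDc = 3,
                             seed = 41, condition = "steady_state")
  cfgB <- makeRecoveryConfig(0.25, nNk = 8, nDc = 3, seed = 42,
                             condition = "LPS")
  simA <- simulateFov(cfgA, 1); simB <- simulateFov(cfgB, 2)
  fovs <- list(simA$fov, simB$fov)
  events <- rbind(detectAll(simA$fov), detectAll(simB$fov))
  cs <- cohortSummary(fovs, events)
  expect_setequal(cs$condition, c("steady_state", "LPS"))
  a <- cs[cs$condition == "steady_state", ]
  expect_equal(a$n_nk_tracked, 8)
  expect_gte(a$n_nk_interacting, 4)   # the 4 planted cells at least
  expect_equal(a$interacting_pct, 100 * a$n_nk_interacting / 8)
  expect_equal(a$long_pct_of_interacting,
               100 * a$n_long / a$n_nk_interacting)
  expect_equal(a$long_pct_of_tracked, 100 * a$n_long / 8)
  expect_true(is.finite(a$velocity_mean_um_min))
})
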
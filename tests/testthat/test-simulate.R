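test_that("simulation is bit-identical under a fixed seed and differs across seeds", {
  cfg <- makeRecoveryConfig(0.3, nNk = 10, nDc = 3, seed = 9)
  a <- simulateFov(cfg, 1)
  b <- simulateFov(cfg, 1)
  expect_identical(lapply(trajectories(a$fov), trackPoints),
                   lapply(trajectories(b$fov), trackPoints))
  expect_identical(a$truth, b$truth)
  c <- simulateFov(cfg, 2)
  expect_false(identical(trackPoints(trajectories(a$fov)$NK001),
                         trackPoints(trajectories(c$fov)$NK001)))
})

test_that("enforced separation keeps every NK-DC pair beyond 2d and yields no events", {
  cfg <- makeNullConfig(seed = 4, nNk = 10, nDc = 4, separationUm = 50)
  sim <- simulateFov(cfg, 1)
  fov <- sim$fov
  expect_identical(nrow(sim$truth), 0L)
  for (nkId in cellIds(fov, "NK")) for (dcId in cellIds(fov, "DC")) {
    pd <- pairDistance(trajectories(fov)[[nkId]], trajectories(fov)[[dcId]])
    expect_gte(min(pd$dist_um), 50)
  }
  expect_identical(nrow(detectAll(fov)), 0L)
})

test_that("a noiseless planted 30-frame episode is detected with exactly 900 s", {
  ep <- data.frame(nk_id = "NK001", dc_id = "DC001", start_frame = 40L,
                   n_frames = 30L, dwell_dist_um = 12.5,
                   dwell_speed_frac = 0.15)
  cfg <- SimulationConfig(seed = 2, nNk = 4, nDc = 2, episodes = ep)
  sim <- simulateFov(cfg, 1)
  ev <- detectAll(sim$fov)
  hit <- ev[ev$nk_id == "NK001" & ev$dc_id == "DC001" &
              ev$start_frame == 40, , drop = FALSE]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$n_frames, 30L)
  expect_equal(hit$duration_s, 900)
  expect_equal(hit$class, "long")
  expect_identical(sim$truth$class, "long")
})

test_that("episode configuration errors are caught at construction", {
  epBad <- data.frame(nk_id = "NK099", dc_id = "DC001", start_frame = 10L,
                      n_frames = 5L, dwell_dist_um = 12.5,
                      dwell_speed_frac = 0.15)
  expect_error(SimulationConfig(nNk = 4, nDc = 2, episodes = epBad),
               "nonexistent NK")
  epOverlap <- data.frame(nk_id = "NK001", dc_id = c("DC001", "DC002"),
                          start_frame = c(10L, 12L), n_frames = c(10L, 5L),
                          dwell_dist_um = 12.5, dwell_speed_frac = 0.15)
  expect_error(SimulationConfig(nNk = 4, nDc = 2, episodes = epOverlap),
               "overlapping")
  epLate <- data.frame(nk_id = "NK001", dc_id = "DC001", start_frame = 115L,
                       n_frames = 10L, dwell_dist_um = 12.5,
                       dwell_speed_frac = 0.15)
  expect_error(SimulationConfig(nNk = 4, nDc = 2, nFrames = 120L,
                                episodes = epLate), "past the last frame")
})

test_that("addNoise: identity at zero, reproducible, binomial frame survival", {
  cfg <- SimulationConfig(seed = 6, nNk = 4, nDc = 1, nFrames = 100L)
  fov <- simulateFov(cfg, 1)$fov
  expect_identical(addNoise(fov, 0, 0, seed = 1), fov)
  n1 <- addNoise(fov, jitterSdUm = 0.5, dropP = 0.2, seed = 7)
  n2 <- addNoise(fov, jitterSdUm = 0.5, dropP = 0.2, seed = 7)
  expect_identical(lapply(trajectories(n1), trackPoints),
                   lapply(trajectories(n2), trackPoints))
  expect_false(identical(trackPoints(trajectories(n1)$NK001),
                         trackPoints(trajectories(fov)$NK001)))

  set.seed(55)
  counts <- unlist(lapply(1:30, function(i) {
    vapply(trajectories(addNoise(fov, 0, 0.5, seed = i)), nPoints, integer(1))
  }))
  # survival should match Binomial(100, 0.5): mean within 4 sd of 50
  expect_lt(abs(mean(counts) - 50), 4 * 5 / sqrt(length(counts)))
})

test_that("write -> detect round trip works on simulator output", {
  cfg <- makeRecoveryConfig(0.5, nNk = 6, nDc = 2, seed = 12)
  sim <- simulateFov(cfg, 1)
  dir <- withr::local_tempdir()
  writeTracks(sim$fov, file.path(dir, "tracks.csv"))
  back <- readTracks(file.path(dir, "tracks.csv"))[[1]]
  expect_equal(frameInterval(back), 30)
  evA <- detectAll(sim$fov)
  evB <- detectAll(back)
  expect_equal(evB[, -1], evA[, -1], tolerance = 1e-5)
})

test_that("runSimulate and runDetect produce conformant, rerunnable outputs", {
  dir <- withr::local_tempdir()
  cfgPath <- file.path(dir, "sim.yaml")
  yaml::write_yaml(list(seed = 3, n_nk = 6, n_dc = 2, n_frames = 80,
                        episodes = list(list(nk_id = "NK001",
                                             dc_id = "DC001",
                                             start_frame = 30,
                                             n_frames = 10))), cfgPath)
  out1 <- file.path(dir, "run1"); out2 <- file.path(dir, "run2")
  res <- runSimulate(cfgPath, out1)
  expect_true(file.exists(file.path(out1, "tracks.csv")))
  expect_true(file.exists(file.path(out1, "ground_truth.tsv")))
  runSimulate(cfgPath, out2)
  expect_identical(readLines(file.path(out1, "tracks.csv")),
                   readLines(file.path(out2, "tracks.csv")))

  det <- runDetect(file.path(out1, "tracks.csv"), NULL,
                   file.path(dir, "det"), diagnostics = TRUE)
  expect_true(any(det$events$nk_id == "NK001" & det$events$n_frames == 10))
  js <- jsonlite::read_json(file.path(dir, "det", "cohort_summary.json"))
  expect_equal(js$detector$distance_threshold_um, 25)
  expect_true(file.exists(file.path(dir, "det", "diagnostics.tsv")))
  expect_true(file.exists(file.path(dir, "det", "manifest.json")))

  bad <- file.path(dir, "bad.csv")
  writeLines("fov_id,condition\na,b", bad)
  expect_error(runDetect(bad, NULL, file.path(dir, "detbad")), "missing column")
})
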
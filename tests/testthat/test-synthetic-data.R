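test_that("generators are deterministic under a fixed seed and differ across seeds", {
  cfg <- syntheticConfig(n_frames = 5, rng_seed = 1)
  expect_identical(makeStructuralTemplate(cfg), makeStructuralTemplate(cfg))
  expect_identical(makeDeformationSequence(cfg), makeDeformationSequence(cfg))
  ex1 <- generateSyntheticExperiment(cfg)
  ex2 <- generateSyntheticExperiment(cfg)
  expect_identical(activityChannel(ex1$movie), activityChannel(ex2$movie))
  expect_identical(ex1$flow, ex2$flow)

  cfgB <- syntheticConfig(n_frames = 5, rng_seed = 2)
  tA <- makeStructuralTemplate(cfg); tB <- makeStructuralTemplate(cfgB)
  expect_gt(mean(tA != tB), 0.01)
})

test_that("structural template is nonnegative with bright blobs over background", {
  cfg <- syntheticConfig(n_frames = 5, n_blobs = 20, rng_seed = 3)
  tpl <- makeStructuralTemplate(cfg)
  expect_gte(min(tpl), 0)
  expect_gt(max(tpl), 0.3)          # blobs rise well above the 0.1 background
  expect_equal(dim(tpl), c(64, 64))
})

test_that("deformation sequences respect amplitude, zero reference and smoothness", {
  cfg0 <- syntheticConfig(n_frames = 6, deformation_amplitude = 0, rng_seed = 1)
  expect_true(all(vapply(makeDeformationSequence(cfg0),
                         function(f) all(f == 0), logical(1))))

  cfg <- syntheticConfig(n_frames = 8, deformation_amplitude = 3,
                         deformation_smoothness = 8, rng_seed = 4)
  fields <- makeDeformationSequence(cfg)
  expect_true(all(fields[[1]] == 0))
  mags <- vapply(fields, function(f) max(sqrt(f[, , 1]^2 + f[, , 2]^2)),
                 numeric(1))
  expect_lte(max(mags), 3 + 1e-9)

  # small-amplitude fields stay clear of the divergence artifact criterion
  cfg1 <- syntheticConfig(n_frames = 8, deformation_amplitude = 1, rng_seed = 5)
  for (f in makeDeformationSequence(cfg1)) {
    # finite-difference divergence oracle, written out directly
    d1 <- f[, , 1]; d2 <- f[, , 2]
    h <- nrow(d1); w <- ncol(d1)
    dv <- (rbind(d1[2:h, ], d1[h, ]) - rbind(d1[1, ], d1[1:(h - 1), ])) /
      c(1, rep(2, h - 2), 1) +
      (cbind(d2[, 2:w], d2[, w]) - cbind(d2[, 1], d2[, 1:(w - 1)])) /
      rep(c(1, rep(2, w - 2), 1), each = h)
    expect_gt(min(dv), -1.2)
    expect_false(detectArtifacts(f)$flagged)
  }
})

test_that("warping by a field then its negation returns the template", {
  cfg <- syntheticConfig(n_frames = 4, deformation_amplitude = 1.5,
                         rng_seed = 6)
  tpl <- makeStructuralTemplate(cfg)
  f <- makeDeformationSequence(cfg)[[3]]
  back <- warpFrame(warpFrame(tpl, f), -f)
  rng <- diff(range(tpl))
  interior <- back[5:60, 5:60] - tpl[5:60, 5:60]
  expect_lt(mean(abs(interior)), 0.02 * rng)
})

test_that("rendered movies follow the multiplicative activity model", {
  # gain = 0: activity channel equals structural channel exactly (no noise)
  cfg <- syntheticConfig(n_frames = 6, gain = 0, noise_sd = 0,
                         deformation_amplitude = 0,
                         event_times = list(left = 0.2, right = numeric(0)),
                         rng_seed = 7)
  ex <- generateSyntheticExperiment(cfg)
  expect_equal(activityChannel(ex$movie), structuralChannel(ex$movie))

  # single planted transient, no noise/deformation: peak within one frame of
  # the onset, halved one half-life later (closed-form exponential)
  hl <- 1.1448
  cfg2 <- syntheticConfig(n_frames = 64, frame_rate = 8, gain = 1,
                          noise_sd = 0, deformation_amplitude = 0,
                          event_times = list(left = 5, right = numeric(0)),
                          cir_half_life = hl, rng_seed = 8)
  ex2 <- generateSyntheticExperiment(cfg2)
  mask <- ex2$ground_truth$masks$left
  px <- which(mask, arr.ind = TRUE)[1, ]
  trace <- activityChannel(ex2$movie)[px[1], px[2], ] /
    structuralChannel(ex2$movie)[px[1], px[2], ] - 1
  t <- frameTimes(ex2$movie)
  expect_lte(abs(t[which.max(trace)] - 5), 1 / 8)
  peak <- max(trace)
  atHalf <- trace[which.min(abs(t - (5 + hl)))]
  expect_lt(abs(atHalf / peak - 0.5), 0.06)

  # structural mean is constant over time within 3 SE under noise only
  cfg3 <- syntheticConfig(n_frames = 40, noise_sd = 0.02,
                          deformation_amplitude = 0, rng_seed = 9)
  ex3 <- generateSyntheticExperiment(cfg3)
  m <- apply(structuralChannel(ex3$movie), 3, mean)
  se <- 0.02 / sqrt(64 * 64)
  expect_true(all(abs(m - mean(m)) < 3 * se + 1e-12))
})

test_that("ground truth bookkeeping matches the planted events", {
  cfg <- syntheticConfig(n_frames = 40,
                         event_times = list(left = c(1, 3), right = 2),
                         rng_seed = 1)
  gt <- makeGroundTruth(cfg)
  expect_identical(gt$true_event_onsets$left, c(1, 3))
  expect_identical(gt$true_event_onsets$right, 2)
  expect_true(all(gt$true_fields[[1]] == 0))
})

test_that("optic flow traces encode the behavior schedule", {
  sched <- data.frame(state = c("walk_fwd", "walk_bwd", "turn_left"),
                      start = c(1, 4, 7), end = c(3, 6, 9))
  cfg <- syntheticConfig(n_frames = 80, frame_rate = 8, flow_noise_sd = 0,
                         behavior_schedule = sched, rng_seed = 1)
  flow <- makeOpticFlow(makeGroundTruth(cfg), cfg)
  vel <- suppressWarnings(convertOpticFlow(flow))
  mid <- function(a, b) vel$t > a + 0.3 & vel$t < b - 0.3
  expect_equal(mean(vel$v_forward[mid(1, 3)]), 0.5 * 31.42, tolerance = 1e-6)
  expect_lt(max(vel$v_forward[mid(4, 6)]), 0)
  expect_true(all(flow$yaw[flow$t >= 7 & flow$t < 9] < 0))

  # all-still schedule with zero noise gives all-zero traces
  cfg0 <- syntheticConfig(n_frames = 20, flow_noise_sd = 0, rng_seed = 1)
  flow0 <- makeOpticFlow(makeGroundTruth(cfg0), cfg0)
  expect_true(all(flow0$ap == 0 & flow0$ml == 0 & flow0$yaw == 0))
})

test_that("behavior frames move only in the scheduled region", {
  sched <- data.frame(state = c("walk_fwd", "groom"),
                      start = c(1, 4), end = c(3, 6))
  cfg <- syntheticConfig(n_frames = 64, frame_rate = 8,
                         behavior_schedule = sched, rng_seed = 2)
  vid <- makeBehaviorFrames(makeGroundTruth(cfg), cfg)
  stillIdx <- which(vid$states == "still")
  k <- stillIdx[stillIdx > 1][5]
  expect_identical(vid$frames[, , k], vid$frames[, , k - 1])

  walkIdx <- which(vid$states == "walk_fwd")[5]
  df <- abs(vid$frames[, , walkIdx] - vid$frames[, , walkIdx - 1])
  rw <- vid$roi_walk
  expect_gt(sum(df[rw[1]:rw[2], rw[3]:rw[4]] > 0), 400)

  groomIdx <- which(vid$states == "groom")[5]
  dg <- abs(vid$frames[, , groomIdx] - vid$frames[, , groomIdx - 1])
  rg <- vid$roi_groom
  outside <- dg
  outside[rg[1]:rg[2], rg[3]:rg[4]] <- 0
  expect_equal(sum(outside > 0), 0)
})

test_that("invalid synthetic configurations are rejected", {
  expect_error(syntheticConfig(image_height = 4), "dimensions")
  expect_error(syntheticConfig(deformation_amplitude = -1), "amplitude")
  expect_error(syntheticConfig(behavior_schedule = data.frame(
    state = "hop", start = 0, end = 1)), "unknown behavior state")
  expect_error(syntheticConfig(behavior_schedule = data.frame(
    state = c("still", "groom"), start = c(0, 1), end = c(2, 3)),
    n_frames = 100), "non-overlapping")
})
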
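test_that("the class threshold is a linear-interpolation percentile of pooled derivatives", {
  flat <- ratioTraceOf(rep(2, 50))
  expect_equal(poolDerivativeThreshold(flat, 97.5), 0)

  # construct a trace whose derivative values are exactly 1..100
  x <- c(0, cumsum(1:100))
  tr <- data.frame(t = seq_along(x) - 1, percent_dRR = x)
  expect_equal(poolDerivativeThreshold(tr, 90), 90.1)

  # pooling is order-free
  a <- ratioTraceOf(cumsum(runif(40)))
  b <- ratioTraceOf(cumsum(runif(60)))
  expect_equal(poolDerivativeThreshold(list(a, b), 97.5),
               poolDerivativeThreshold(list(b, a), 97.5))
})

test_that("event onsets are the zero-crossings preceding threshold crossings", {
  cfgE <- eventConfig()
  # monotone non-increasing trace: no events
  down <- ratioTraceOf(seq(100, 0, length.out = 400))
  expect_equal(nEvents(detectEvents(down, 1, cfgE)), 0)

  # single planted exponential transient at t = 20 s on a 60 s trace
  fr <- 8
  t <- seq(0, 60 - 1 / fr, by = 1 / fr)
  x <- ifelse(t >= 20, 80 * exp(-log(2) * (t - 20) / 1.1448), 0)
  tr <- data.frame(t = t, percent_dRR = x)
  ev <- detectEvents(tr, poolDerivativeThreshold(tr, 97.5), cfgE)
  expect_equal(nEvents(ev), 1)
  expect_lte(abs(eventOnsets(ev) - 20), 2 / fr)
  # brute-force derivative scan oracle: the onset is the last sample with
  # non-positive derivative before the largest derivative
  d <- diff(x) * fr
  kMax <- which.max(d)
  jOracle <- max(which(d[1:kMax] <= 0))
  expect_equal(eventOnsets(ev), t[jOracle])

  # transient at 5 s is inside the edge-exclusion zone
  x2 <- ifelse(t >= 5 & t < 15, 80 * exp(-log(2) * (t - 5) / 1.1448), 0)
  ev2 <- detectEvents(data.frame(t = t, percent_dRR = x2),
                      poolDerivativeThreshold(tr, 97.5), cfgE)
  expect_equal(nEvents(ev2), 0)

  # every onset precedes its triggering crossing (asserted by construction)
  set.seed(8)
  noisy <- ratioTraceOf(cumsum(rnorm(500)) + 50, rate = 8)
  th <- poolDerivativeThreshold(noisy, 90)
  evN <- detectEvents(noisy, th, cfgE)
  d <- diff(noisy$percent_dRR) / diff(noisy$t)
  for (on in eventOnsets(evN)) {
    j <- which(noisy$t == on)
    expect_lte(d[j], 0)
  }
})

test_that("bilateral reconciliation applies the covarying and independent rules", {
  tr <- c(0, 100)
  cfgC <- eventConfig(covarying_pair = TRUE)
  cfgI <- eventConfig(covarying_pair = FALSE)

  # covarying: a unilateral event is copied to the partner
  r1 <- reconcileBilateral(EventSeries(10, tRange = tr),
                           EventSeries(numeric(0), tRange = tr), cfgC)
  expect_equal(eventOnsets(r1$left), 10)
  expect_equal(eventOnsets(r1$right), 10)
  expect_equal(eventSource(r1$right), "copied_from_partner")

  # covarying: both retained when within 2 s, nothing copied
  r2 <- reconcileBilateral(EventSeries(10, tRange = tr),
                           EventSeries(11, tRange = tr), cfgC)
  expect_equal(eventOnsets(r2$left), 10)
  expect_equal(eventOnsets(r2$right), 11)
  expect_true(all(eventSource(r2$left) == "detected"))
  expect_true(all(eventSource(r2$right) == "detected"))

  # independent: both removed when within 0.25 s
  r3 <- reconcileBilateral(EventSeries(10.0, tRange = tr),
                           EventSeries(10.1, tRange = tr), cfgI)
  expect_equal(nEvents(r3$left), 0)
  expect_equal(nEvents(r3$right), 0)
  expect_equal(r3$left@vetoed, 10.0)
  expect_equal(r3$right@vetoed, 10.1)

  # copies that would land in the partner's edge-exclusion zone are dropped
  r4 <- reconcileBilateral(EventSeries(c(5, 50), tRange = tr),
                           EventSeries(numeric(0), tRange = tr), cfgC)
  expect_equal(eventOnsets(r4$right), 50)

  # conservation: covarying never deletes, independent never creates
  set.seed(9)
  for (i in 1:10) {
    L <- EventSeries(sort(runif(8, 11, 89)) + seq(0, 1e-6, length.out = 8),
                     tRange = tr)
    R <- EventSeries(sort(runif(6, 11, 89)) + seq(0, 1e-6, length.out = 6),
                     tRange = tr)
    rc <- reconcileBilateral(L, R, cfgC)
    expect_true(all(eventOnsets(L) %in% eventOnsets(rc$left)))
    expect_true(all(eventOnsets(R) %in% eventOnsets(rc$right)))
    ri <- reconcileBilateral(L, R, cfgI)
    expect_true(all(eventOnsets(ri$left) %in% eventOnsets(L)))
    expect_true(all(eventOnsets(ri$right) %in% eventOnsets(R)))
  }
})

test_that("event-triggered summaries are baselined at 0 s with percentile-bootstrap CIs", {
  fr <- 100
  t <- seq(0, 100, by = 1 / fr)
  dRR <- data.frame(t = t, percent_dRR = 5 + 3 * sin(t / 3))
  vel <- data.frame(t = t, v_forward = cos(t / 5))
  cfgE <- eventConfig(n_bootstrap = 100)

  one <- eventTriggeredSummary(EventSeries(50, tRange = range(t)),
                               list(d = dRR, v = vel), cfgE, seed = 1)
  z <- which.min(abs(one$t_rel))
  expect_equal(one$signals$percent_dRR$mean[z], 0)
  expect_equal(one$signals$percent_dRR$ci_lo, one$signals$percent_dRR$mean)
  # single event: the mean is that window
  expect_equal(one$signals$v_forward$mean,
               approx(t, vel$v_forward, 50 + one$t_rel)$y, tolerance = 1e-9)

  ev <- EventSeries(c(20, 40, 60, 80), tRange = range(t))
  s <- eventTriggeredSummary(ev, list(d = dRR, v = vel), cfgE, seed = 1)
  expect_equal(s$signals$percent_dRR$mean[z], 0)
  expect_true(all(s$signals$v_forward$ci_lo <= s$signals$v_forward$mean + 1e-12))
  expect_true(all(s$signals$v_forward$ci_hi >= s$signals$v_forward$mean - 1e-12))

  # constant signals: zero-width CI
  cs <- eventTriggeredSummary(ev, list(v = data.frame(t = t, v_forward = 2)),
                              cfgE, seed = 1)
  expect_true(all(cs$signals$v_forward$ci_hi - cs$signals$v_forward$ci_lo == 0))
  expect_true(all(cs$signals$v_forward$mean == 2))

  expect_error(eventTriggeredSummary(EventSeries(3, tRange = range(t)),
                                     list(d = dRR), cfgE), "full")
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n) for homogeneous events", {
  fr <- 50
  t <- seq(0, 2200, by = 1 / fr)
  set.seed(10)
  sig <- data.frame(t = t, v_forward = rnorm(length(t)))
  cfgE <- eventConfig(n_bootstrap = 200, summary_rate = 50)
  ev10 <- EventSeries(seq(20, 2180, length.out = 10), tRange = range(t))
  ev40 <- EventSeries(seq(20, 2180, length.out = 40), tRange = range(t))
  w10 <- with(eventTriggeredSummary(ev10, list(v = sig), cfgE, 1)$signals$v_forward,
              mean(ci_hi - ci_lo))
  w40 <- with(eventTriggeredSummary(ev40, list(v = sig), cfgE, 1)$signals$v_forward,
              mean(ci_hi - ci_lo))
  expect_equal(w10 / w40, 2, tolerance = 0.35)
})

test_that("shuffled controls are deterministic per seed and flat on periodic signals", {
  fr <- 100
  t <- seq(0, 600, by = 1 / fr)
  sig <- data.frame(t = t, v_forward = sin(2 * pi * t / 7))
  cfgE <- eventConfig(n_bootstrap = 100)
  s1 <- shuffledControl(list(v = sig), 400, cfgE, seed = 5)
  s2 <- shuffledControl(list(v = sig), 400, cfgE, seed = 5)
  expect_identical(s1, s2)
  expect_lt(max(abs(s1$signals$v_forward$mean)), 0.1 * 1)
  expect_error(shuffledControl(list(v = sig), 0, cfgE), "n_events")
})

test_that("exemplar ranking follows the per-behavior treadmill statistics", {
  t <- seq(0, 100, by = 0.01)
  vf <- numeric(length(t))
  # two backward episodes of different depth after events at 30 and 60 s
  vf[t >= 30 & t < 32] <- -3
  vf[t >= 60 & t < 62] <- -8
  vel <- data.frame(t = t, v_forward = vf, v_side = 0, v_rotation = 0)
  ev <- EventSeries(c(30, 60), tRange = range(t))
  rk <- selectExemplarEvents(ev, vel, "backward")
  expect_equal(rk$onset[1], 60)

  # symmetric yaw pair ranks oppositely under the two yaw criteria
  vr <- numeric(length(t))
  vr[t >= 30 & t < 32] <- 90
  vr[t >= 60 & t < 62] <- -90
  velY <- data.frame(t = t, v_forward = 0, v_side = 0, v_rotation = vr)
  expect_equal(selectExemplarEvents(ev, velY, "yaw_left")$onset[1], 30)
  expect_equal(selectExemplarEvents(ev, velY, "yaw_right")$onset[1], 60)

  # push-down: biggest before-vs-after forward-velocity difference first
  vp <- numeric(length(t))
  vp[t >= 30 & t < 32] <- 5
  vp[t >= 60 & t < 62] <- 1
  velP <- data.frame(t = t, v_forward = vp, v_side = 0, v_rotation = 0)
  expect_equal(selectExemplarEvents(ev, velP, "push_down")$onset[1], 30)

  # single event is trivially top-ranked; out-of-window events are skipped
  expect_equal(nrow(selectExemplarEvents(EventSeries(50, tRange = range(t)),
                                         vel, "backward")), 1)
  expect_warning(
    rs <- selectExemplarEvents(EventSeries(c(0.5, 50), tRange = range(t)),
                               vel, "backward"), "skipped")
  expect_equal(nrow(rs), 1)
})

test_that("the event pipeline recovers frequent planted transients", {
  cfg <- eventRichConfig(seed = 11)
  ex <- generateSyntheticExperiment(cfg)
  trL <- extractRatioTrace(ex$movie, ex$ground_truth$masks$left, roi_label = "left")
  trR <- extractRatioTrace(ex$movie, ex$ground_truth$masks$right, roi_label = "right")
  th <- poolDerivativeThreshold(list(trL, trR), 97.5)
  cfgE <- eventConfig()
  evL <- detectEvents(trL, th, cfgE)
  planted <- cfg$event_times$left
  usable <- planted[planted >= 10 & planted <= cfg$duration - 10]
  # in sampled data the onset (start of the rise) is the sample before the
  # first elevated frame
  expected <- usable - 1 / cfg$frame_rate
  err <- vapply(expected, function(on) min(abs(eventOnsets(evL) - on)),
                numeric(1))
  recall <- mean(err <= 0.5)
  expect_gte(recall, 0.9)
  # matched onsets are on average within 2 samples of the true onsets
  expect_lte(mean(err[err <= 0.5]), 2 / cfg$frame_rate + 1e-9)
  # false events: detections far from any planted onset
  false_ev <- sum(vapply(eventOnsets(evL),
                         function(on) min(abs(expected - on)) > 0.5,
                         logical(1)))
  expect_lte(false_ev / length(usable), 0.1)
})
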
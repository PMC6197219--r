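test_that("warpFrame matches direct index shifting and round-trips", {
  cfg <- syntheticConfig(n_frames = 4, rng_seed = 1)
  tpl <- makeStructuralTemplate(cfg)
  expect_identical(warpFrame(tpl, array(0, c(64, 64, 2))), tpl)

  wp <- warpFrame(tpl, uniformField(64, 64, 3, -2))
  # index-shift oracle on the interior
  expect_equal(wp[1:60, 3:64], tpl[4:63, 1:62])

  expect_error(warpFrame(tpl, array(0, c(32, 32, 2))), "shape")
})

test_that("block matching recovers translations and rejects featureless input", {
  cfg <- syntheticConfig(n_frames = 4, rng_seed = 2)
  tpl <- makeStructuralTemplate(cfg)

  mId <- computeMatches(tpl, tpl)
  expect_gt(nrow(mId), 5)
  expect_true(all(mId$m1 == 0 & mId$m2 == 0))

  frame <- warpFrame(tpl, uniformField(64, 64, 3, -2))
  m <- computeMatches(tpl, frame)
  expect_equal(median(m$m1), -3)
  expect_equal(median(m$m2), 2)
  # independent exhaustive integer-shift oracle at one keypoint
  kp <- m[1, ]
  best <- c(NA, NA); bestScore <- -Inf
  patch <- tpl[(kp$row - 4):(kp$row + 4), (kp$col - 4):(kp$col + 4)]
  for (di in -8:8) for (dj in -8:8) {
    r <- kp$row + di; c <- kp$col + dj
    if (r < 5 || r > 60 || c < 5 || c > 60) next
    q <- frame[(r - 4):(r + 4), (c - 4):(c + 4)]
    sc <- suppressWarnings(cor(as.vector(patch), as.vector(q)))
    if (is.finite(sc) && sc > bestScore) { bestScore <- sc; best <- c(di, dj) }
  }
  expect_equal(unname(c(kp$m1, kp$m2)), best)

  expect_equal(nrow(computeMatches(matrix(1, 64, 64), matrix(1, 64, 64))), 0)
  expect_error(computeMatches(tpl, tpl[1:32, 1:32]), "shape")
})

test_that("identical reference and frame is a zero-motion fixed point", {
  cfg <- syntheticConfig(n_frames = 4, rng_seed = 3)
  tpl <- makeStructuralTemplate(cfg)
  for (lam in c(1, 2000)) {
    w <- estimateMotion(tpl, tpl, params = registrationParams(lambda = lam))
    expect_lt(max(abs(w)), 0.1)
  }
})

test_that("a pure translation is recovered to sub-pixel accuracy", {
  cfg <- syntheticConfig(n_frames = 4, rng_seed = 4)
  tpl <- makeStructuralTemplate(cfg)
  frame <- warpFrame(tpl, uniformField(64, 64, 3, -2))
  # the field registering frame back to the reference is (-3, 2)
  w <- estimateMotion(tpl, frame,
                      params = registrationParams(lambda = 2000, gamma = 1))
  epe <- sqrt((w[, , 1] + 3)^2 + (w[, , 2] - 2)^2)
  expect_lt(mean(epe), 0.5)
})

test_that("the outer energy trace is monotone non-increasing", {
  cfg <- syntheticConfig(n_frames = 6, deformation_amplitude = 2, rng_seed = 5)
  ex <- generateSyntheticExperiment(cfg)
  str <- structuralChannel(ex$movie)
  w <- estimateMotion(str[, , 1], str[, , 4],
                      params = registrationParams(lambda = 50))
  en <- attr(w, "energies")
  expect_gt(length(en), 1)
  expect_true(all(diff(en) <= 1e-6 * pmax(abs(en[-length(en)]), 1)))
})

test_that("non-finite images are rejected", {
  img <- matrix(1, 16, 16)
  bad <- img; bad[3, 3] <- NaN
  expect_error(estimateMotion(img, bad), "NaN")
})

test_that("artifact detection matches analytic divergence and an independent recomputation", {
  # zero field: nothing to report
  rep0 <- detectArtifacts(array(0, c(32, 32, 2)))
  expect_length(rep0$sizes, 0)
  expect_false(rep0$flagged)

  # uniform translation: divergence identically zero
  repT <- detectArtifacts(uniformField(32, 32, 2, -1))
  expect_true(all(repT$divergence == 0))
  expect_false(repT$flagged)

  # radial sink w(x) = -0.8 (x - c): analytic divergence -1.6 in the interior
  f <- array(0, c(32, 32, 2))
  for (r in 13:19) for (c in 13:19) {
    f[r, c, 1] <- -0.8 * (r - 16); f[r, c, 2] <- -0.8 * (c - 16)
  }
  repS <- detectArtifacts(f)
  expect_true(repS$flagged)
  expect_equal(length(repS$sizes), 1)
  expect_gt(max(repS$sizes), 20)
  expect_equal(repS$divergence[16, 16], -1.6)

  # brute-force recomputation oracle on random smooth fields
  set.seed(42)
  for (i in 1:8) {
    g <- array(rnorm(24 * 24 * 2, sd = 2), c(24, 24, 2))
    g[, , 1] <- as.matrix(EBImage::gblur(g[, , 1], 1.5))
    g[, , 2] <- as.matrix(EBImage::gblur(g[, , 2], 1.5))
    rep <- detectArtifacts(g)
    # independent divergence: central differences written out directly
    d1 <- g[, , 1]; d2 <- g[, , 2]; h <- 24; w <- 24
    ddr <- rbind(d1[2, ] - d1[1, ],
                 (d1[3:h, ] - d1[1:(h - 2), ]) / 2,
                 d1[h, ] - d1[h - 1, ])
    ddc <- cbind(d2[, 2] - d2[, 1],
                 (d2[, 3:w] - d2[, 1:(w - 2)]) / 2,
                 d2[, w] - d2[, w - 1])
    dv <- ddr + ddc
    expect_equal(rep$divergence, dv)
    lab <- ccLabelOracle(dv < -1.2)
    sizes <- if (max(lab) > 0) tabulate(lab[lab > 0]) else integer(0)
    expect_setequal(rep$sizes, sizes)
    expect_identical(rep$flagged, any(sizes > 20))
  }
})

test_that("registration quality is the mean gradient of the temporal mean image", {
  cfg <- syntheticConfig(n_frames = 4, rng_seed = 6)
  tpl <- makeStructuralTemplate(cfg)
  still <- array(tpl, c(64, 64, 3))
  q <- registrationQuality(still)
  # direct recomputation on the single frame
  h <- 64; w <- 64
  gr <- rbind(tpl[2, ] - tpl[1, ], (tpl[3:h, ] - tpl[1:(h - 2), ]) / 2,
              tpl[h, ] - tpl[h - 1, ])
  gc <- cbind(tpl[, 2] - tpl[, 1], (tpl[, 3:w] - tpl[, 1:(w - 2)]) / 2,
              tpl[, w] - tpl[, w - 1])
  expect_equal(q, mean(sqrt(gr^2 + gc^2)))

  expect_equal(registrationQuality(array(0.5, c(16, 16, 3))), 0)
  expect_error(registrationQuality(array(0.5, c(16, 16, 1))), "2 frames")
})

test_that("grid search excludes artifact-prone parameters and breaks ties upward", {
  cfg <- syntheticConfig(n_frames = 3, deformation_amplitude = 0,
                         noise_sd = 0, rng_seed = 7)
  ex <- generateSyntheticExperiment(cfg)

  # single artifact-free grid point is returned as-is
  p1 <- gridSearchRegistration(ex$movie, 500, 1, frame_stride = 1)
  expect_equal(p1$lambda, 500)

  # identical frames: equal quality everywhere, tie goes to the larger lambda
  p2 <- gridSearchRegistration(ex$movie, c(500, 3000), 1, frame_stride = 1)
  expect_equal(p2$lambda, 3000)

  # a crafted movie in which a bright blob dims strongly: a loose smoothness
  # weight explains the dimming by contracting the blob (a divergence
  # artifact), a stiff one stays clean and wins despite the residual
  tpl <- makeStructuralTemplate(cfg)
  g <- expand.grid(r = 1:64, c = 1:64)
  blob <- matrix(exp(-((g$r - 32)^2 + (g$c - 32)^2) / (2 * 4^2)), 64, 64)
  frames <- array(0, c(64, 64, 3))
  frames[, , 1] <- tpl + 1.5 * blob
  frames[, , 2] <- tpl + 0.15 * blob
  frames[, , 3] <- tpl + 0.15 * blob
  movie <- TwoChannelMovie(frames, frames, 8)
  p3 <- gridSearchRegistration(movie, c(20, 2000), 1, frame_stride = 1)
  expect_equal(p3$lambda, 2000)
  grid <- attr(p3, "grid")
  expect_gt(grid$n_flagged[grid$lambda == 20], 0)
  expect_equal(grid$n_flagged[grid$lambda == 2000], 0)

  expect_error(gridSearchRegistration(ex$movie, numeric(0), 1), "empty grid")
})

test_that("solver energy matches brute-force enumeration on tiny instances", {
  # 8x8 instances with blockwise integer ground truth; the oracle
  # exhaustively enumerates all fields constant on the 2x2 block grid with
  # components in {-1, 0, 1}
  lam <- 10
  grid <- as.matrix(expand.grid(rep(list(-1:1), 8)))
  set.seed(19)
  for (trial in 1:3) {
    v <- sample(-1:1, 8, replace = TRUE)
    frame <- tinyTexture(8, seed = trial)
    ref <- warpFrame(frame, blockyField(v))
    w <- estimateMotion(ref, frame, emptyMatchSet(),
                        registrationParams(lambda = lam, gamma = 0))
    eS <- registrationEnergy(w, ref, frame, emptyMatchSet(), lam, 0)
    eB <- Inf
    for (i in seq_len(nrow(grid))) {
      e <- registrationEnergy(blockyField(as.numeric(grid[i, ])), ref, frame,
                              emptyMatchSet(), lam, 0)
      if (e < eB) eB <- e
    }
    expect_lte(eS, eB + 1e-6)
  }
})
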
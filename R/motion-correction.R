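# Non-rigid motion correction of the structural channel.
#
# Each frame I_t is registered to a reference I_r by minimizing
#
#   E(w) = sum_x |I_t(x + w(x)) - I_r(x)|
#        + gamma * sum_keypoints ||w(x) - m(x)||_1
#        + lambda * sum_x ||grad w(x)||_2^2
#
# over per-pixel displacement fields w. The l1 data term gives partial
# robustness to intensity changes; the feature term pulls the field toward
# sparse block-matching correspondences m computed on the structural
# (activity-independent) channel; the quadratic gradient penalty promotes
# smoothness. The energy is minimized by ADMM with two splitting variables
# (one for the smoothness term, one for the feature term), each sub-problem
# solved in closed form, inside a warp-and-linearize outer loop over a
# coarse-to-fine image pyramid.

#' Registration parameters
#'
#' @param lambda smoothness weight (> 0) on the 8-bit-normalized intensity
#'   scale (see [registrationEnergy()]). Small values (below ~1000)
#'   occasionally produce convergence artifacts in the field; larger values
#'   suit coarser deformations.
#' @param gamma feature-matching weight (>= 0).
#' @param admm_penalty ADMM penalty parameter (> 0), fixed across iterations.
#' @param max_iterations cap on outer (warp-and-linearize) iterations per
#'   pyramid level.
#' @param convergence_tol relative energy change below which the outer loop
#'   stops.
#' @param median_filter_radius radius of the weighted median post-filter
#'   (2 gives the 5x5 window); 0 disables it.
#' @param pyramid_levels number of coarse-to-fine levels (each half size).
#' @param inner_iterations ADMM sweeps per outer iteration.
#' @return validated list of class \code{"RegistrationParams"}.
#' @export
registrationParams <- function(lambda = 2000, gamma = 1, admm_penalty = 10,
                               max_iterations = 100, convergence_tol = 1e-4,
                               median_filter_radius = 2, pyramid_levels = 3,
                               inner_iterations = 8) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (admm_penalty <= 0) stop("admm_penalty must be > 0")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  structure(list(lambda = lambda, gamma = gamma, admm_penalty = admm_penalty,
                 max_iterations = max_iterations,
                 convergence_tol = convergence_tol,
                 median_filter_radius = median_filter_radius,
                 pyramid_levels = pyramid_levels,
                 inner_iterations = inner_iterations),
            class = "RegistrationParams")
}

#' Warp a frame by a motion field
#'
#' Returns the frame sampled at \code{x + w(x)} with bilinear interpolation
#' and edge clamping. A zero field returns the input exactly.
#'
#' @param frame numeric matrix.
#' @param field motion field array \code{[h, w, 2]} (row, col displacement).
#' @return warped numeric matrix.
#' @export
warpFrame <- function(frame, field) {
  if (!identical(dim(frame), dim(field)[1:2]))
    stop("frame and field shapes differ")
  if (all(field == 0)) return(frame)
  g <- coordGrid(nrow(frame), ncol(frame))
  matrix(bilinearSample(frame, as.vector(g$r + field[, , 1]),
                        as.vector(g$c + field[, , 2])),
         nrow(frame), ncol(frame))
}

#' Sparse feature correspondences by block matching
#'
#' Normalized-cross-correlation block matching on a regular keypoint grid
#' restricted to high-gradient locations of the structural channel. Stands
#' in for a published descriptor matcher: the contract is sparse reliable
#' correspondences robust to intensity change, feeding the feature term of
#' the registration energy.
#'
#' @param reference,frame structural-channel images of identical shape.
#' @param step keypoint grid spacing (px).
#' @param patch_radius half-size of the matching patch.
#' @param search_radius maximum displacement searched (px, integer grid).
#' @param gradient_floor minimum mean gradient magnitude in the reference
#'   patch, as a fraction of the reference dynamic range.
#' @param score_floor minimum correlation score for a match to be kept.
#' @return data.frame of class \code{"MatchSet"} with columns
#'   \code{row, col, m1, m2, score}; zero rows if no keypoint qualifies.
#' @export
computeMatches <- function(reference, frame, step = 8, patch_radius = 4,
                           search_radius = 8, gradient_floor = 0.02,
                           score_floor = 0.5) {
  if (!identical(dim(reference), dim(frame)))
    stop("images of different shape")
  h <- nrow(reference); w <- ncol(reference)
  pr <- patch_radius; sr <- search_radius
  empty <- structure(data.frame(row = numeric(0), col = numeric(0),
                                m1 = numeric(0), m2 = numeric(0),
                                score = numeric(0)), class = c("MatchSet",
                                                               "data.frame"))
  dr <- diff(range(reference))
  if (dr == 0) return(empty)
  margin <- pr + 1
  rows <- seq(margin, h - margin, by = step)
  cols <- seq(margin, w - margin, by = step)
  if (!length(rows) || !length(cols)) return(empty)
  grad <- imageGradient(reference)
  gmag <- sqrt(grad$dr^2 + grad$dc^2)
  off <- as.matrix(expand.grid(dr = -pr:pr, dc = -pr:pr))
  shifts <- as.matrix(expand.grid(di = -sr:sr, dj = -sr:sr))
  out <- list()
  for (r in rows) for (c in cols) {
    pidx <- cbind(r + off[, 1], c + off[, 2])
    if (mean(gmag[pidx]) < gradient_floor * dr) next
    P <- reference[pidx]
    P <- P - mean(P)
    np <- sqrt(sum(P^2))
    if (np == 0) next
    best <- -Inf; bi <- 0L; bj <- 0L
    for (s in seq_len(nrow(shifts))) {
      ri <- r + shifts[s, 1]; cj <- c + shifts[s, 2]
      if (ri - pr < 1 || ri + pr > h || cj - pr < 1 || cj + pr > w) next
      Q <- frame[cbind(ri + off[, 1], cj + off[, 2])]
      Q <- Q - mean(Q)
      nq <- sqrt(sum(Q^2))
      if (nq == 0) next
      sc <- sum(P * Q) / (np * nq)
      if (sc > best) { best <- sc; bi <- shifts[s, 1]; bj <- shifts[s, 2] }
    }
    if (is.finite(best) && best >= score_floor)
      out[[length(out) + 1]] <- c(r, c, bi, bj, best)
  }
  if (!length(out)) return(empty)
  m <- do.call(rbind, out)
  structure(data.frame(row = m[, 1], col = m[, 2], m1 = m[, 3], m2 = m[, 4],
                       score = m[, 5]),
            class = c("MatchSet", "data.frame"))
}

#' Registration energy of a motion field
#'
#' Evaluates the variational objective (l1 data term + feature term +
#' quadratic smoothness). Intensities are normalized to an 8-bit-equivalent
#' dynamic range (0-255, set by the reference image) before the data term
#' is computed, so that lambda and gamma values are comparable across
#' acquisitions with different intensity scales.
#'
#' @param w motion field \code{[h, w, 2]}.
#' @param reference,frame images.
#' @param matches a [computeMatches()] result.
#' @param lambda,gamma energy weights.
#' @return scalar energy.
#' @export
registrationEnergy <- function(w, reference, frame, matches, lambda, gamma) {
  dr <- diff(range(reference))
  s <- if (dr > 0) 255 / dr else 1
  .registrationEnergyRaw(w, reference * s, frame * s, matches, lambda, gamma)
}

# Energy on already-normalized intensities.
.registrationEnergyRaw <- function(w, reference, frame, matches, lambda,
                                   gamma) {
  warped <- warpFrame(frame, w)
  e <- sum(abs(warped - reference))
  if (gamma > 0 && nrow(matches)) {
    idx <- cbind(matches$row, matches$col)
    e <- e + gamma * sum(abs(w[, , 1][idx] - matches$m1) +
                         abs(w[, , 2][idx] - matches$m2))
  }
  for (k in 1:2) {
    M <- w[, , k]
    h <- nrow(M); ww <- ncol(M)
    if (h > 1) e <- e + lambda * sum((M[2:h, ] - M[1:(h - 1), ])^2)
    if (ww > 1) e <- e + lambda * sum((M[, 2:ww] - M[, 1:(ww - 1)])^2)
  }
  e
}

# Single-scale ADMM solve (warp-and-linearize outer loop). `w0` is the
# initial field; matches may have zero rows. Returns list(field, energies).
estimateMotionSingleScale <- function(reference, frame, matches, params, w0) {
  h <- nrow(reference); w <- ncol(reference)
  mu <- params$admm_penalty; lambda <- params$lambda; gamma <- params$gamma
  g <- coordGrid(h, w)
  gradF <- imageGradient(frame)
  hasKp <- gamma > 0 && nrow(matches) > 0
  if (hasKp) {
    kpIdx <- cbind(matches$row, matches$col)
    m1 <- matches$m1; m2 <- matches$m2
  }
  W1 <- w0[, , 1]; W2 <- w0[, , 2]
  Z11 <- W1; Z12 <- W2; U11 <- matrix(0, h, w); U12 <- matrix(0, h, w)
  if (hasKp) {
    z21 <- W1[kpIdx]; z22 <- W2[kpIdx]
    u21 <- numeric(nrow(matches)); u22 <- numeric(nrow(matches))
  }
  curField <- function() { f <- array(0, c(h, w, 2)); f[, , 1] <- W1
                           f[, , 2] <- W2; f }
  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  eBest <- .registrationEnergyRaw(curField(), reference, frame, matches,
                              lambda, gamma)
  energies <- eBest
  bestW1 <- W1; bestW2 <- W2
  for (outer in seq_len(params$max_iterations)) {
    # linearize the data term around the current field
    rr <- as.vector(g$r + W1); cc <- as.vector(g$c + W2)
    Iw <- matrix(bilinearSample(frame, rr, cc), h, w)
    Gr <- matrix(bilinearSample(gradF$dr, rr, cc), h, w)
    Gc <- matrix(bilinearSample(gradF$dc, rr, cc), h, w)
    C0 <- Iw - reference
    L1 <- W1; L2 <- W2   # linearization point
    g2 <- Gr^2 + Gc^2
    for (inner in seq_len(params$inner_iterations)) {
      # w-update: per-pixel closed form (soft threshold along the gradient)
      V1 <- Z11 - U11; V2 <- Z12 - U12
      muEff <- matrix(mu, h, w)
      if (hasKp) {
        V1[kpIdx] <- (V1[kpIdx] + z21 - u21) / 2
        V2[kpIdx] <- (V2[kpIdx] + z22 - u22) / 2
        muEff[kpIdx] <- 2 * mu
      }
      r <- C0 + Gr * (V1 - L1) + Gc * (V2 - L2)
      th <- g2 / muEff
      lo <- r < -th; hi <- r > th; mid <- !(lo | hi) & g2 > 1e-12
      W1 <- V1; W2 <- V2
      W1[lo] <- V1[lo] + Gr[lo] / muEff[lo]
      W2[lo] <- V2[lo] + Gc[lo] / muEff[lo]
      W1[hi] <- V1[hi] - Gr[hi] / muEff[hi]
      W2[hi] <- V2[hi] - Gc[hi] / muEff[hi]
      W1[mid] <- V1[mid] - r[mid] * Gr[mid] / g2[mid]
      W2[mid] <- V2[mid] - r[mid] * Gc[mid] / g2[mid]
      # z1-update: screened Poisson (smoothness term), exact
      Z11 <- screenedPoissonSolve(mu * (W1 + U11), mu, lambda)
      Z12 <- screenedPoissonSolve(mu * (W2 + U12), mu, lambda)
      # z2-update: shrinkage toward the matches (feature term)
      if (hasKp) {
        t1 <- W1[kpIdx] + u21; t2 <- W2[kpIdx] + u22
        z21 <- m1 + soft(t1 - m1, gamma / mu)
        z22 <- m2 + soft(t2 - m2, gamma / mu)
        u21 <- t1 - z21; u22 <- t2 - z22
      }
      U11 <- U11 + W1 - Z11
      U12 <- U12 + W2 - Z12
      # track the best (lowest-energy) iterate: raw ADMM iterates are not
      # monotone in the true energy, the recorded outer sequence is
      e <- .registrationEnergyRaw(curField(), reference, frame, matches,
                              lambda, gamma)
      if (e < eBest) { eBest <- e; bestW1 <- W1; bestW2 <- W2 }
    }
    ePrev <- energies[length(energies)]
    energies <- c(energies, eBest)
    if (ePrev - eBest <= params$convergence_tol * max(abs(ePrev), 1e-12))
      break
    # re-linearize the data term around the best iterate found so far
    W1 <- bestW1; W2 <- bestW2
  }
  list(field = { f <- array(0, c(h, w, 2)); f[, , 1] <- bestW1
                 f[, , 2] <- bestW2; f },
       energies = energies)
}

# Large-move refinement: tries uniform integer displacement offsets on
# whole tiles of the field (coarse-to-fine tilings), accepting a move when
# it lowers the energy. Under a uniform offset only the tile's data term,
# its boundary smoothness edges and its keypoints change, so the energy
# delta is computed locally and exactly. Greedy sequential acceptance keeps
# the energy non-increasing. Lets the solver escape basins where a whole
# region sits at the wrong displacement. Images must be pre-normalized.
tileFusionRefine <- function(field, reference, frame, matches, lambda, gamma,
                             tilings = list(c(1, 1), c(1, 2), c(2, 1),
                                            c(2, 2), c(4, 4)),
                             max_range = 1, max_sweeps = 10) {
  h <- nrow(reference); w <- ncol(reference)
  g <- coordGrid(h, w)
  hasKp <- gamma > 0 && nrow(matches) > 0
  offs <- expand.grid(d1 = -max_range:max_range, d2 = -max_range:max_range)
  offs <- offs[!(offs$d1 == 0 & offs$d2 == 0), ]
  W1 <- field[, , 1]; W2 <- field[, , 2]
  # cost of a tile under candidate displacement maps (C1, C2): data term
  # within the tile, boundary smoothness edges, in-tile keypoint terms
  tileCost <- function(rows, cols, C1, C2) {
    rr <- g$r[rows, cols] + C1[rows, cols]
    cc <- g$c[rows, cols] + C2[rows, cols]
    e <- sum(abs(bilinearSample(frame, as.vector(rr), as.vector(cc)) -
                 as.vector(reference[rows, cols])))
    r0 <- rows[1]; r1 <- rows[length(rows)]
    c0 <- cols[1]; c1 <- cols[length(cols)]
    edge <- function(rA, cA, rB, cB)
      sum((C1[cbind(rA, cA)] - W1[cbind(rB, cB)])^2 +
          (C2[cbind(rA, cA)] - W2[cbind(rB, cB)])^2)
    s <- 0
    if (r0 > 1) s <- s + edge(rep(r0, length(cols)), cols,
                              rep(r0 - 1, length(cols)), cols)
    if (r1 < h) s <- s + edge(rep(r1, length(cols)), cols,
                              rep(r1 + 1, length(cols)), cols)
    if (c0 > 1) s <- s + edge(rows, rep(c0, length(rows)),
                              rows, rep(c0 - 1, length(rows)))
    if (c1 < w) s <- s + edge(rows, rep(c1, length(rows)),
                              rows, rep(c1 + 1, length(rows)))
    e <- e + lambda * s
    if (hasKp) {
      inT <- matches$row >= r0 & matches$row <= r1 &
             matches$col >= c0 & matches$col <= c1
      if (any(inT)) {
        idx <- cbind(matches$row[inT], matches$col[inT])
        e <- e + gamma * sum(abs(C1[idx] - matches$m1[inT]) +
                             abs(C2[idx] - matches$m2[inT]))
      }
    }
    e
  }
  for (tl in tilings) {
    nr <- tl[1]; nc <- tl[2]
    rB <- round(seq(0, h, length.out = nr + 1))
    cB <- round(seq(0, w, length.out = nc + 1))
    for (sweep in seq_len(max_sweeps)) {
      moved <- FALSE
      for (i in seq_len(nr)) for (j in seq_len(nc)) {
        rows <- (rB[i] + 1):rB[i + 1]; cols <- (cB[j] + 1):cB[j + 1]
        cur <- tileCost(rows, cols, W1, W2)
        best <- cur; B1 <- NULL; B2 <- NULL
        for (k in seq_len(nrow(offs))) {
          # offset move: shift the tile's current field uniformly
          C1 <- W1; C2 <- W2
          C1[rows, cols] <- C1[rows, cols] + offs$d1[k]
          C2[rows, cols] <- C2[rows, cols] + offs$d2[k]
          e <- tileCost(rows, cols, C1, C2)
          if (e < best - 1e-12) { best <- e; B1 <- C1; B2 <- C2 }
        }
        for (d1 in -max_range:max_range) for (d2 in -max_range:max_range) {
          # reset move: make the tile constant at an integer vector
          C1 <- W1; C2 <- W2
          C1[rows, cols] <- d1; C2[rows, cols] <- d2
          e <- tileCost(rows, cols, C1, C2)
          if (e < best - 1e-12) { best <- e; B1 <- C1; B2 <- C2 }
        }
        if (!is.null(B1)) { W1 <- B1; W2 <- B2; moved <- TRUE }
      }
      if (!moved) break
    }
  }
  out <- array(0, dim(field)); out[, , 1] <- W1; out[, , 2] <- W2
  out
}

# Discrete local refinement of a field by iterated conditional modes on the
# true (non-linearized) energy: each pixel's displacement is moved to the
# best of a small set of offsets given its neighbors, in a red-black sweep
# so updates are exact coordinate descent. Energy is non-increasing by
# construction. Catches pixel-scale structure that the linearized ADMM
# steps cannot reach. Images must already be on the normalized scale.
icmRefine <- function(field, reference, frame, matches, lambda, gamma,
                      steps = c(1, 0.5, 0.25), sweeps = 2) {
  h <- nrow(reference); w <- ncol(reference)
  g <- coordGrid(h, w)
  W1 <- field[, , 1]; W2 <- field[, , 2]
  hasKp <- gamma > 0 && nrow(matches) > 0
  Gm1 <- matrix(NA_real_, h, w); Gm2 <- matrix(NA_real_, h, w)
  if (hasKp) {
    Gm1[cbind(matches$row, matches$col)] <- matches$m1
    Gm2[cbind(matches$row, matches$col)] <- matches$m2
  }
  color <- (g$r + g$c) %% 2
  # local cost of candidate displacements (d1, d2) at every pixel
  localCost <- function(D1, D2) {
    dat <- abs(matrix(bilinearSample(frame, as.vector(g$r + D1),
                                     as.vector(g$c + D2)), h, w) - reference)
    sm <- matrix(0, h, w)
    sm[2:h, ] <- sm[2:h, ] + (D1[2:h, ] - W1[1:(h - 1), ])^2 +
                             (D2[2:h, ] - W2[1:(h - 1), ])^2
    sm[1:(h - 1), ] <- sm[1:(h - 1), ] + (D1[1:(h - 1), ] - W1[2:h, ])^2 +
                                         (D2[1:(h - 1), ] - W2[2:h, ])^2
    sm[, 2:w] <- sm[, 2:w] + (D1[, 2:w] - W1[, 1:(w - 1)])^2 +
                             (D2[, 2:w] - W2[, 1:(w - 1)])^2
    sm[, 1:(w - 1)] <- sm[, 1:(w - 1)] + (D1[, 1:(w - 1)] - W1[, 2:w])^2 +
                                         (D2[, 1:(w - 1)] - W2[, 2:w])^2
    cost <- dat + lambda * sm
    if (hasKp) {
      kp <- !is.na(Gm1)
      cost[kp] <- cost[kp] + gamma * (abs(D1[kp] - Gm1[kp]) +
                                      abs(D2[kp] - Gm2[kp]))
    }
    cost
  }
  for (s in seq_len(sweeps)) for (step in steps) {
    offs <- expand.grid(d1 = c(-step, 0, step), d2 = c(-step, 0, step))
    for (col in 0:1) {
      upd <- color == col
      bestC <- localCost(W1, W2)
      b1 <- W1; b2 <- W2
      for (k in seq_len(nrow(offs))) {
        if (offs$d1[k] == 0 && offs$d2[k] == 0) next
        cst <- localCost(W1 + offs$d1[k], W2 + offs$d2[k])
        take <- upd & (cst < bestC)
        bestC[take] <- cst[take]
        b1[take] <- W1[take] + offs$d1[k]
        b2[take] <- W2[take] + offs$d2[k]
      }
      W1 <- b1; W2 <- b2
    }
  }
  out <- array(0, dim(field)); out[, , 1] <- W1; out[, , 2] <- W2
  out
}

# Weighted median filter of a field; weights are a Gaussian of the
# structural-intensity difference to the window center.
weightedMedianField <- function(field, reference, radius = 2,
                                sigma_frac = 0.1) {
  if (radius <= 0) return(field)
  h <- dim(field)[1]; w <- dim(field)[2]
  sigma <- sigma_frac * max(diff(range(reference)), 1e-12)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  n <- nrow(offs)
  g <- coordGrid(h, w)
  vals1 <- matrix(0, h * w, n); vals2 <- matrix(0, h * w, n)
  wts <- matrix(0, h * w, n)
  ctr <- as.vector(reference)
  for (k in seq_len(n)) {
    ri <- pmin(pmax(as.vector(g$r) + offs$dr[k], 1), h)
    ci <- pmin(pmax(as.vector(g$c) + offs$dc[k], 1), w)
    idx <- cbind(ri, ci)
    vals1[, k] <- field[, , 1][idx]
    vals2[, k] <- field[, , 2][idx]
    wts[, k] <- exp(-((reference[idx] - ctr)^2) / (2 * sigma^2))
  }
  out <- array(0, dim(field))
  out[, , 1] <- matrix(rowWeightedMedian(vals1, wts), h, w)
  out[, , 2] <- matrix(rowWeightedMedian(vals2, wts), h, w)
  out
}

#' Estimate the motion field registering a frame to a reference
#'
#' Minimizes the l1-data + feature-matching + quadratic-smoothness energy by
#' ADMM within a warp-and-linearize loop over a coarse-to-fine pyramid, then
#' applies a weighted median post-filter (kept only when it does not
#' increase the energy). The energy at successive outer iterates is
#' non-increasing by construction (a non-decreasing step is rejected and the
#' loop stops).
#'
#' @param reference,frame structural-channel images of identical shape.
#' @param matches a [computeMatches()] result (possibly empty).
#' @param params a [registrationParams()].
#' @return motion field array \code{[h, w, 2]} with attributes
#'   \code{"energies"} (finest-level outer-iteration energy trace) and
#'   \code{"converged"}.
#' @export
estimateMotion <- function(reference, frame,
                           matches = computeMatches(reference, frame),
                           params = registrationParams()) {
  if (!identical(dim(reference), dim(frame)))
    stop("images of different shape")
  if (anyNA(reference) || anyNA(frame) || !all(is.finite(reference)) ||
      !all(is.finite(frame)))
    stop("NaN or non-finite values in images")
  # normalize intensities to the 8-bit-equivalent scale of the energy
  drange <- diff(range(reference))
  s <- if (drange > 0) 255 / drange else 1
  reference <- reference * s; frame <- frame * s
  nlev <- params$pyramid_levels
  while (nlev > 1 && min(dim(reference)) / 2^(nlev - 1) < 12) nlev <- nlev - 1
  refs <- list(reference); frms <- list(frame)
  for (l in seq_len(nlev - 1)) {
    refs[[l + 1]] <- halveImage(refs[[l]])
    frms[[l + 1]] <- halveImage(frms[[l]])
  }
  w <- NULL
  for (l in nlev:1) {
    hl <- nrow(refs[[l]]); wl <- ncol(refs[[l]])
    if (is.null(w)) {
      # global integer-translation pre-alignment at the coarsest level
      ml0 <- scaleMatches(matches, 1 / 2^(l - 1), hl, wl)
      w <- array(0, c(hl, wl, 2))
      eBest <- .registrationEnergyRaw(w, refs[[l]], frms[[l]], ml0,
                                      params$lambda, params$gamma)
      for (d1 in -2:2) for (d2 in -2:2) {
        if (d1 == 0 && d2 == 0) next
        cand <- array(0, c(hl, wl, 2))
        cand[, , 1] <- d1; cand[, , 2] <- d2
        e <- .registrationEnergyRaw(cand, refs[[l]], frms[[l]], ml0,
                                    params$lambda, params$gamma)
        if (e < eBest) { eBest <- e; w <- cand }
      }
    } else {
      up <- array(0, c(hl, wl, 2))
      up[, , 1] <- 2 * resizeBilinear(w[, , 1], hl, wl)
      up[, , 2] <- 2 * resizeBilinear(w[, , 2], hl, wl)
      w <- up
    }
    ml <- scaleMatches(matches, 1 / 2^(l - 1), hl, wl)
    fit <- estimateMotionSingleScale(refs[[l]], frms[[l]], ml, params, w)
    w <- fit$field
    if (l == 1) energies <- fit$energies
  }
  # large-move tile refinement, then per-pixel discrete refinement, both
  # exact coordinate descent on the true energy (non-increasing)
  w <- tileFusionRefine(w, reference, frame, matches, params$lambda,
                        params$gamma)
  w <- icmRefine(w, reference, frame, matches, params$lambda, params$gamma)
  if (params$median_filter_radius > 0) {
    wf <- weightedMedianField(w, reference, params$median_filter_radius)
    eRaw <- .registrationEnergyRaw(w, reference, frame, matches,
                                   params$lambda, params$gamma)
    eFilt <- .registrationEnergyRaw(wf, reference, frame, matches,
                                    params$lambda, params$gamma)
    if (eFilt <= eRaw + 1e-9) w <- wf
  }
  converged <- length(energies) < params$max_iterations + 1 ||
    abs(diff(utils::tail(energies, 2))) <=
      params$convergence_tol * max(abs(energies[length(energies) - 1]), 1e-12)
  if (!converged)
    warning("estimateMotion: outer loop hit max_iterations without converging")
  attr(w, "energies") <- energies
  attr(w, "converged") <- converged
  w
}

# Rescale a MatchSet to a pyramid level (factor <= 1); deduplicates rounded
# keypoints keeping the best score.
scaleMatches <- function(matches, factor, h, w) {
  if (is.null(matches) || !nrow(matches) || factor == 1) {
    if (!is.null(matches) && nrow(matches)) return(matches)
    return(structure(data.frame(row = numeric(0), col = numeric(0),
                                m1 = numeric(0), m2 = numeric(0),
                                score = numeric(0)),
                     class = c("MatchSet", "data.frame")))
  }
  m <- data.frame(row = pmin(pmax(round((matches$row - 1) * factor + 1), 1), h),
                  col = pmin(pmax(round((matches$col - 1) * factor + 1), 1), w),
                  m1 = matches$m1 * factor, m2 = matches$m2 * factor,
                  score = matches$score)
  m <- m[order(-m$score), ]
  m <- m[!duplicated(m[, c("row", "col")]), ]
  structure(m, class = c("MatchSet", "data.frame"))
}

# 4-connected components of a logical mask; returns an integer label matrix.
connectedComponents4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- ((p - 1) %% h) + 1; c <- ((p - 1) %/% h) + 1
      for (q in c(if (r > 1) p - 1, if (r < h) p + 1,
                  if (c > 1) p - h, if (c < w) p + h)) {
        if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  lab
}

#' Detect convergence artifacts in a motion field
#'
#' Registration failures appear as strong local sinks in the field. The
#' detector computes the divergence by central finite differences,
#' thresholds it, and finds 4-connected clusters; any cluster larger than
#' \code{min_cardinality} pixels flags the field.
#'
#' @param field motion field \code{[h, w, 2]}.
#' @param threshold divergence threshold (default -1.2).
#' @param min_cardinality cluster size above which the field is flagged
#'   (default 20; similar results are obtained with 5).
#' @return list of class \code{"ArtifactReport"}: \code{clusters} (list of
#'   pixel-index matrices), \code{sizes}, \code{flagged}, \code{divergence}.
#' @export
detectArtifacts <- function(field, threshold = -1.2, min_cardinality = 20) {
  if (!all(is.finite(field))) stop("field must be finite")
  dv <- divergenceField(field)
  mask <- dv < threshold
  lab <- connectedComponents4(mask)
  ncl <- max(lab)
  clusters <- lapply(seq_len(ncl), function(k) which(lab == k, arr.ind = TRUE))
  sizes <- vapply(clusters, nrow, integer(1))
  structure(list(clusters = clusters, sizes = sizes,
                 flagged = any(sizes > min_cardinality), divergence = dv),
            class = "ArtifactReport")
}

#' Registration quality: gradient of the temporal mean image
#'
#' Sharpness of the temporal mean of the registered structural channel,
#' measured as the mean gradient magnitude. Well-registered movies give a
#' sharper mean image, hence a higher value.
#'
#' @param movie a [TwoChannelMovie-class] (structural channel is used) or a
#'   \code{[h, w, T]} array.
#' @return scalar quality.
#' @export
registrationQuality <- function(movie) {
  arr <- if (is(movie, "TwoChannelMovie")) structuralChannel(movie) else movie
  if (length(dim(arr)) != 3 || dim(arr)[3] < 2)
    stop("registrationQuality needs at least 2 frames")
  mean_img <- apply(arr, c(1, 2), mean)
  grad <- imageGradient(mean_img)
  mean(sqrt(grad$dr^2 + grad$dc^2))
}

#' Register a movie to a reference frame
#'
#' Estimates a motion field per frame of the structural channel and applies
#' it to both channels.
#'
#' @param movie a [TwoChannelMovie-class].
#' @param params a [registrationParams()].
#' @param reference_frame index of the reference frame (default 1).
#' @param frames optional subset of frame indices to register (others are
#'   skipped; used by the grid search).
#' @return list with \code{movie} (registered [TwoChannelMovie-class] over
#'   the selected frames), \code{fields} (list of estimated fields), and
#'   \code{frames} (the indices used).
#' @export
registerMovie <- function(movie, params = registrationParams(),
                          reference_frame = 1, frames = NULL) {
  stopifnot(is(movie, "TwoChannelMovie"))
  str <- structuralChannel(movie); act <- activityChannel(movie)
  nT <- dim(str)[3]
  if (is.null(frames)) frames <- seq_len(nT)
  ref <- str[, , reference_frame]
  fields <- vector("list", length(frames))
  regS <- array(0, c(dim(str)[1:2], length(frames)))
  regA <- regS
  for (i in seq_along(frames)) {
    t <- frames[i]
    if (t == reference_frame) {
      fields[[i]] <- array(0, c(dim(str)[1:2], 2))
      regS[, , i] <- str[, , t]; regA[, , i] <- act[, , t]
      next
    }
    m <- computeMatches(ref, str[, , t])
    w <- estimateMotion(ref, str[, , t], m, params)
    fields[[i]] <- w
    regS[, , i] <- warpFrame(str[, , t], w)
    regA[, , i] <- warpFrame(act[, , t], w)
  }
  list(movie = TwoChannelMovie(regA, regS, frameRate(movie)),
       fields = fields, frames = frames)
}

#' Grid search over registration parameters
#'
#' Registers a frame subsample of the movie at every (lambda, gamma) grid
#' point, excludes parameter pairs whose estimated fields produce any
#' flagged artifact report, and among the survivors returns the pair with
#' the highest registration quality (sharpest temporal mean). If every pair
#' is flagged, the pair with the fewest flagged frames wins. Ties go to the
#' larger lambda.
#'
#' @param movie a [TwoChannelMovie-class].
#' @param lambda_grid,gamma_grid numeric vectors of candidate values.
#' @param frame_stride register every \code{frame_stride}-th frame.
#' @param params_base base [registrationParams()] supplying the remaining
#'   settings.
#' @return the selected [registrationParams()], with a \code{"grid"}
#'   attribute holding the per-candidate diagnostics.
#' @export
gridSearchRegistration <- function(movie, lambda_grid, gamma_grid,
                                   frame_stride = 5,
                                   params_base = registrationParams()) {
  if (!length(lambda_grid) || !length(gamma_grid)) stop("empty grid")
  frames <- unique(c(1, seq(1, nFrames(movie), by = frame_stride)))
  cand <- expand.grid(lambda = lambda_grid, gamma = gamma_grid)
  cand$quality <- NA_real_; cand$n_flagged <- NA_integer_
  for (i in seq_len(nrow(cand))) {
    p <- params_base
    p$lambda <- cand$lambda[i]; p$gamma <- cand$gamma[i]
    reg <- registerMovie(movie, p, frames = frames)
    flags <- vapply(reg$fields, function(f) detectArtifacts(f)$flagged,
                    logical(1))
    cand$n_flagged[i] <- sum(flags)
    cand$quality[i] <- registrationQuality(reg$movie)
  }
  clean <- cand[cand$n_flagged == 0, , drop = FALSE]
  pool <- if (nrow(clean)) clean else
    cand[cand$n_flagged == min(cand$n_flagged), , drop = FALSE]
  crit <- if (nrow(clean)) pool$quality else -pool$n_flagged
  best <- pool[crit == max(crit), , drop = FALSE]
  best <- best[order(-best$lambda), , drop = FALSE][1, ]
  out <- params_base
  out$lambda <- best$lambda; out$gamma <- best$gamma
  attr(out, "grid") <- cand
  out
}
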
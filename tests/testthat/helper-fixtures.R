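# Shared fixtures, built in code.

emptyMatchSet <- function() {
  structure(data.frame(row = numeric(0), col = numeric(0), m1 = numeric(0),
                       m2 = numeric(0), score = numeric(0)),
            class = c("MatchSet", "data.frame"))
}

uniformField <- function(h, w, d1, d2) {
  f <- array(0, c(h, w, 2)); f[, , 1] <- d1; f[, , 2] <- d2
  f
}

# field piecewise constant on a 2 x 2 arrangement of blocks; v is the
# 8-vector (d1, d2) per block in row-major block order
blockyField <- function(v, n = 8) {
  half <- n / 2
  f <- array(0, c(n, n, 2))
  blocks <- list(list(1:half, 1:half), list(1:half, (half + 1):n),
                 list((half + 1):n, 1:half),
                 list((half + 1):n, (half + 1):n))
  for (b in 1:4) {
    f[blocks[[b]][[1]], blocks[[b]][[2]], 1] <- v[2 * b - 1]
    f[blocks[[b]][[1]], blocks[[b]][[2]], 2] <- v[2 * b]
  }
  f
}

# small rough textured image for tiny registration instances
tinyTexture <- function(n = 8, seed = 7) {
  set.seed(seed)
  img <- matrix(runif(n * n, 0.1, 1), n, n)
  as.matrix(EBImage::gblur(img, 1)) + 0.05 * matrix(runif(n * n), n, n)
}

# independent connected-component labelling (union-find, 4-connectivity),
# used as the oracle against the package's flood fill
ccLabelOracle <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  parent <- seq_len(h * w)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (c in seq_len(w)) for (r in seq_len(h)) {
    if (!mask[r, c]) next
    i <- (c - 1) * h + r
    if (r > 1 && mask[r - 1, c]) union(i, i - 1)
    if (c > 1 && mask[r, c - 1]) union(i, i - h)
  }
  lab <- matrix(0L, h, w)
  roots <- vapply(which(mask), find, numeric(1))
  lab[which(mask)] <- as.integer(factor(roots))
  lab
}

# ratio trace with a prescribed %dR/R signal at a given rate
ratioTraceOf <- function(x, rate = 8, t0 = 0) {
  out <- data.frame(t = t0 + (seq_along(x) - 1) / rate, percent_dRR = x)
  class(out) <- c("RatioTrace", "data.frame")
  out
}

# synthetic transient-rich experiment shared by the event-pipeline tests:
# frequent planted events (one per ~4 s, as in transient-rich recordings)
# so that rise samples make up over 2.5% of the pooled derivative mass and
# the 97.5th-percentile class threshold sits at transient level, above noise
eventRichConfig <- function(seed = 11, n_frames = 1120, frame_rate = 8,
                            noise_sd = 0.01) {
  dur <- n_frames / frame_rate
  evL <- seq(15, dur - 15, by = 4.0)
  evR <- evL + 0.12
  syntheticConfig(n_frames = n_frames, frame_rate = frame_rate,
                  deformation_amplitude = 0, noise_sd = noise_sd,
                  event_times = list(left = evL, right = evR),
                  rng_seed = seed)
}
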
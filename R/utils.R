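# Internal numerical helpers shared across modules.
#
# Image convention: a frame is a numeric matrix indexed [row, col]; a movie
# is an array [row, col, frame]. A motion field is an array [row, col, 2]
# holding the row-displacement in [,,1] and the column-displacement in [,,2],
# in pixels, mapping reference coordinates to frame coordinates.

#' Bilinear sampling with edge clamping
#'
#' Samples `img` at real-valued coordinates, clamping coordinates to the
#' image domain so border values extend outward.
#'
#' @param img numeric matrix.
#' @param ri,ci numeric vectors of row/column coordinates (1-based).
#' @return numeric vector of sampled values.
#' @keywords internal
#' @noRd
bilinearSample <- function(img, ri, ci) {
  nr <- nrow(img); nc <- ncol(img)
  ri <- pmin(pmax(ri, 1), nr)
  ci <- pmin(pmax(ci, 1), nc)
  r0 <- pmin(floor(ri), nr - 1L); r1 <- r0 + 1
  c0 <- pmin(floor(ci), nc - 1L); c1 <- c0 + 1
  fr <- ri - r0; fc <- ci - c0
  v00 <- img[cbind(r0, c0)]; v10 <- img[cbind(r1, c0)]
  v01 <- img[cbind(r0, c1)]; v11 <- img[cbind(r1, c1)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Coordinate grids for an h x w image, as matrices.
coordGrid <- function(h, w) {
  list(r = matrix(seq_len(h), h, w), c = matrix(seq_len(w), h, w, byrow = TRUE))
}

# Central-difference gradient with one-sided differences at the borders.
# Returns list(dr, dc): derivative along rows and along columns.
imageGradient <- function(img) {
  h <- nrow(img); w <- ncol(img)
  dr <- img; dc <- img
  if (h > 1) {
    dr[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
    dr[1, ] <- img[2, ] - img[1, ]
    dr[h, ] <- img[h, ] - img[h - 1, ]
  } else dr[] <- 0
  if (w > 1) {
    dc[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
    dc[, 1] <- img[, 2] - img[, 1]
    dc[, w] <- img[, w] - img[, w - 1]
  } else dc[] <- 0
  list(dr = dr, dc = dc)
}

# Divergence of a motion field by central differences (one-sided at borders).
divergenceField <- function(field) {
  stopifnot(length(dim(field)) == 3, dim(field)[3] == 2)
  g1 <- imageGradient(field[, , 1])$dr
  g2 <- imageGradient(field[, , 2])$dc
  g1 + g2
}

# Orthonormal DCT-II matrix of size n (cached); diagonalizes the 1-D
# Laplacian under half-sample-symmetric Neumann boundary conditions.
.dctCache <- new.env(parent = emptyenv())
dctMatrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.dctCache[[key]])) return(.dctCache[[key]])
  j <- 0:(n - 1)
  D <- sqrt(2 / n) * cos(pi * outer(j, j + 0.5) / n)
  D[1, ] <- sqrt(1 / n)
  .dctCache[[key]] <- D
  D
}

# Eigenvalues of the 1-D Neumann 3-point Laplacian in the DCT-II basis.
neumannLaplacianEigen <- function(n) 2 * cos(pi * (0:(n - 1)) / n) - 2

#' Screened Poisson solve under Neumann boundary conditions
#'
#' Solves (mu I - 2 lambda L) z = rhs where L is the 5-point Laplacian with
#' reflecting (Neumann) boundaries, via diagonalization in the DCT-II basis.
#' This is the smoothness sub-problem of the registration ADMM: the exact
#' minimizer of lambda * sum ||forward-difference gradient of z||^2 +
#' (mu/2) * sum (z - v)^2 with rhs = mu * v.
#'
#' @keywords internal
#' @noRd
screenedPoissonSolve <- function(rhs, mu, lambda) {
  h <- nrow(rhs); w <- ncol(rhs)
  Dr <- dctMatrix(h); Dc <- dctMatrix(w)
  Rhat <- Dr %*% rhs %*% t(Dc)
  denom <- mu - 2 * lambda * outer(neumannLaplacianEigen(h),
                                   neumannLaplacianEigen(w), `+`)
  Zhat <- Rhat / denom
  t(Dr) %*% Zhat %*% Dc
}

# Gaussian low-pass filter via FFT (periodic boundary); supports kernel
# scales comparable to the image size, unlike brush-based convolution.
gaussianSmoothFFT <- function(img, sigma) {
  h <- nrow(img); w <- ncol(img)
  fr <- c(0:floor(h / 2), -(ceiling(h / 2) - 1):-1) / h
  fc <- c(0:floor(w / 2), -(ceiling(w / 2) - 1):-1) / w
  G <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  Re(stats::fft(stats::fft(img) * G, inverse = TRUE)) / (h * w)
}

# Centered running mean with window truncated at the edges; k is the
# half-width in samples (window = 2k + 1 where it fits).
runningMeanCentered <- function(x, k) {
  n <- length(x)
  if (k <= 0 || n == 0) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# 2x2 block mean downsampling (pads by edge replication for odd sizes).
halveImage <- function(img) {
  h <- nrow(img); w <- ncol(img)
  if (h %% 2 == 1) img <- rbind(img, img[h, , drop = FALSE])
  if (w %% 2 == 1) img <- cbind(img, img[, ncol(img), drop = FALSE])
  h2 <- nrow(img) / 2; w2 <- ncol(img) / 2
  (img[2 * seq_len(h2) - 1, 2 * seq_len(w2) - 1, drop = FALSE] +
   img[2 * seq_len(h2), 2 * seq_len(w2) - 1, drop = FALSE] +
   img[2 * seq_len(h2) - 1, 2 * seq_len(w2), drop = FALSE] +
   img[2 * seq_len(h2), 2 * seq_len(w2), drop = FALSE]) / 4
}

# Bilinear resize of a matrix to target size (used to upsample fields).
resizeBilinear <- function(img, h2, w2) {
  h <- nrow(img); w <- ncol(img)
  ri <- if (h2 > 1) seq(1, h, length.out = h2) else rep(1, h2)
  ci <- if (w2 > 1) seq(1, w, length.out = w2) else rep(1, w2)
  g <- list(r = matrix(ri, h2, w2), c = matrix(ci, h2, w2, byrow = TRUE))
  matrix(bilinearSample(img, as.vector(g$r), as.vector(g$c)), h2, w2)
}

# Weighted median of rows of `vals` with per-row weights `wts`.
rowWeightedMedian <- function(vals, wts) {
  n <- nrow(vals)
  out <- numeric(n)
  for (i in seq_len(n)) {
    o <- order(vals[i, ])
    v <- vals[i, o]; ww <- wts[i, o]
    cw <- cumsum(ww)
    out[i] <- v[which(cw >= cw[length(cw)] / 2)[1]]
  }
  out
}

# Linear interpolation wrapper with rule-2 clamping disabled: errors outside
# support are the caller's business; interior queries only.
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", ties = "ordered")$y
}

# Normalize a matrix/array to [0, 1] for EBImage calls that expect it.
unitScale <- function(x) {
  rng <- range(x)
  if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
}
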
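# Pixel-wise behavior-regression maps: dF/F target traces regressed on
# behavior sequences convolved with a calcium impulse response.

#' Calcium impulse response kernel
#'
#' Peak-normalized causal exponential \code{exp(-ln2 * t / half_life)}
#' sampled at \code{sample_rate}, truncated at \code{duration}. The default
#' half-life is the GCaMP6s fluorescence decay time constant (1.1448 s).
#'
#' @param half_life decay half-life in seconds.
#' @param sample_rate sampling rate in Hz (the movie frame rate).
#' @param duration kernel duration in seconds (default 5 half-lives).
#' @return list of class \code{"CalciumImpulseResponse"} with \code{kernel}
#'   (first sample 1, non-increasing), \code{times}, \code{half_life},
#'   \code{sample_rate}.
#' @examples
#' cir <- calciumImpulseResponse(sample_rate = 20)
#' cir$kernel[1]            # 1 (peak-normalized)
#' @export
calciumImpulseResponse <- function(half_life = 1.1448, sample_rate,
                                   duration = 5 * half_life) {
  stopifnot(half_life > 0, sample_rate > 0, duration > 0)
  times <- seq(0, duration, by = 1 / sample_rate)
  kernel <- exp(-log(2) * times / half_life)
  structure(list(kernel = kernel, times = times, half_life = half_life,
                 sample_rate = sample_rate),
            class = "CalciumImpulseResponse")
}

#' Pixel-wise dF/F movie
#'
#' The baseline image F is the per-pixel average of ten sequential frames
#' starting at \code{quiescent_start_frame}, chosen where no cellular
#' activity is observed (see [proposeBaselineWindow()] for an automatic
#' proposal). dF/F at frame t is \code{(F_t - F) / F}; pixels whose baseline
#' falls below a positivity floor (a fraction of the movie's dynamic range)
#' are masked out of downstream regression.
#'
#' @param activity \code{[h, w, T]} activity-channel array of a registered
#'   movie.
#' @param quiescent_start_frame first frame of the 10-frame baseline window.
#' @param n_baseline number of baseline frames (default 10).
#' @param floor_frac positivity floor as a fraction of dynamic range
#'   (default 0.01).
#' @return list of class \code{"DffMovie"}: \code{values} \code{[h, w, T]},
#'   \code{baseline}, \code{mask} (TRUE where dF/F is defined).
#' @export
computeDff <- function(activity, quiescent_start_frame = 1, n_baseline = 10,
                       floor_frac = 0.01) {
  d <- dim(activity)
  stopifnot(length(d) == 3)
  if (quiescent_start_frame + n_baseline - 1 > d[3])
    stop("fewer than ", n_baseline, " frames available from frame ",
         quiescent_start_frame)
  idx <- quiescent_start_frame:(quiescent_start_frame + n_baseline - 1)
  F0 <- apply(activity[, , idx, drop = FALSE], c(1, 2), mean)
  floor <- floor_frac * diff(range(activity))
  mask <- F0 > floor
  Fsafe <- ifelse(mask, F0, 1)
  vals <- array(0, d)
  for (t in seq_len(d[3]))
    vals[, , t] <- ifelse(mask, (activity[, , t] - F0) / Fsafe, 0)
  structure(list(values = vals, baseline = F0, mask = mask),
            class = "DffMovie")
}

#' Propose a quiescent baseline window
#'
#' Returns the start frame of the \code{n_baseline}-frame window with
#' minimal and unchanging fluorescence: among the windows in the lowest
#' decile of total intensity (no cellular activity), the one with the
#' smallest total temporal variance. A programmatic stand-in for the manual
#' judgment that no activity is present.
#'
#' @param activity \code{[h, w, T]} array.
#' @param n_baseline window length in frames (default 10).
#' @return integer start frame.
#' @export
proposeBaselineWindow <- function(activity, n_baseline = 10) {
  d <- dim(activity)
  nT <- d[3]
  if (nT < n_baseline) stop("movie shorter than the baseline window")
  px <- matrix(activity, d[1] * d[2], nT)
  starts <- seq_len(nT - n_baseline + 1)
  frameSum <- colSums(px)
  cs <- cumsum(c(0, frameSum))
  winSum <- cs[starts + n_baseline] - cs[starts]
  dim_enough <- winSum <= stats::quantile(winSum, 0.1)
  tv <- vapply(starts, function(s) {
    if (!dim_enough[s]) return(Inf)
    sum(apply(px[, s:(s + n_baseline - 1), drop = FALSE], 1, stats::var))
  }, numeric(1))
  starts[which.min(tv)]
}

#' Build a behavior regressor by CIR convolution
#'
#' Causally convolves a binary behavior sequence with the calcium impulse
#' response kernel, truncated to the sequence length.
#'
#' @param S binary behavior sequence on the movie timebase.
#' @param cir a [calciumImpulseResponse()].
#' @return numeric regressor of \code{length(S)}.
#' @export
buildRegressor <- function(S, cir) {
  stopifnot(inherits(cir, "CalciumImpulseResponse"))
  if (!length(S)) stop("empty behavior sequence")
  stats::convolve(as.numeric(S), rev(cir$kernel), type = "open")[seq_along(S)]
}

#' Pixel-wise univariate regression weights
#'
#' Ordinary least squares with no intercept, per pixel:
#' \code{w = (X'X)^-1 X'y}. Masked pixels receive weight 0.
#'
#' @param X regressor from [buildRegressor()].
#' @param dff a [computeDff()] result.
#' @return numeric weight matrix \code{[h, w]}.
#' @export
fitWeights <- function(X, dff) {
  stopifnot(inherits(dff, "DffMovie"))
  d <- dim(dff$values)
  if (length(X) != d[3]) stop("regressor and movie lengths differ")
  xtx <- sum(X^2)
  if (xtx == 0) stop("degenerate regressor (X'X = 0)")
  Y <- matrix(dff$values, d[1] * d[2], d[3])
  w <- matrix(as.vector(Y %*% X) / xtx, d[1], d[2])
  w[!dff$mask] <- 0
  w
}

#' Normalize a weight map to its maximum
#'
#' Divides by the maximum weight so the map peaks at 1; negative pixels
#' retain their sign. An all-zero map is returned unchanged with attribute
#' \code{"degenerate" = TRUE}.
#'
#' @param map numeric weight matrix.
#' @return normalized matrix.
#' @export
normalizeMap <- function(map) {
  stopifnot(all(is.finite(map)))
  mx <- max(map)
  if (mx == 0 && all(map == 0)) {
    attr(map, "degenerate") <- TRUE
    return(map)
  }
  map / mx
}

#' Mean dF/F trace over a circular ROI
#'
#' @param dff a [computeDff()] result.
#' @param center \code{c(row, col)} of the ROI center.
#' @param radius ROI radius in pixels (default 15).
#' @return numeric per-frame trace.
#' @export
extractMapRoiTrace <- function(dff, center, radius = 15) {
  stopifnot(inherits(dff, "DffMovie"))
  d <- dim(dff$values)
  if (center[1] - radius < 1 || center[1] + radius > d[1] ||
      center[2] - radius < 1 || center[2] + radius > d[2])
    stop("ROI disk out of image bounds")
  g <- coordGrid(d[1], d[2])
  disk <- (g$r - center[1])^2 + (g$c - center[2])^2 <= radius^2
  vapply(seq_len(d[3]), function(t) mean(dff$values[, , t][disk]), numeric(1))
}
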
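# ROI detection, tracking and ratiometric signal extraction for sparse
# neuron imaging (coronal sections through the cervical connective).

#' Detect candidate ROIs on a reference frame
#'
#' Gaussian smoothing to reduce background noise, Otsu threshold,
#' morphological erosion, then connected components; candidates smaller than
#' 3 px are dropped and the rest are returned sorted by decreasing area.
#' Selection among candidates is left to the caller (the programmatic
#' stand-in for manual selection).
#'
#' @param frame single 2-D activity-channel (GCaMP6s) frame.
#' @param smoothing_sigma Gaussian sigma in px (default 2).
#' @param erosion_radius erosion disc radius in px (default 1).
#' @return list of ROI masks (logical matrices), each with attributes
#'   \code{"area"} and \code{"centroid"}; empty list if nothing survives
#'   (callers fall back to [ellipticalRoi()]).
#' @export
detectCandidateRois <- function(frame, smoothing_sigma = 2,
                                erosion_radius = 1) {
  stopifnot(is.matrix(frame))
  if (diff(range(frame)) == 0) return(list())
  sm <- as.matrix(EBImage::gblur(unitScale(frame), sigma = smoothing_sigma))
  sm <- pmin(pmax(sm, 0), 1)
  th <- EBImage::otsu(EBImage::Image(sm))
  bin <- sm > th
  if (erosion_radius > 0)
    bin <- as.matrix(EBImage::erode(
      EBImage::Image(bin * 1),
      EBImage::makeBrush(2 * erosion_radius + 1, shape = "disc"))) > 0
  lab <- connectedComponents4(bin)
  ncl <- max(lab)
  if (ncl == 0) return(list())
  masks <- list()
  for (k in seq_len(ncl)) {
    m <- lab == k
    area <- sum(m)
    if (area < 3) next
    idx <- which(m, arr.ind = TRUE)
    attr(m, "area") <- area
    attr(m, "centroid") <- c(mean(idx[, 1]), mean(idx[, 2]))
    masks[[length(masks) + 1]] <- m
  }
  masks[order(-vapply(masks, function(m) attr(m, "area"), numeric(1)))]
}

#' Track an ROI across frames by cross-correlation
#'
#' For each frame, finds the integer shift of the reference patch
#' (structural channel, bounding box of the mask plus margin) maximizing the
#' normalized cross-correlation within a bounded search window, and
#' translates the reference mask by that shift. Frames whose best score
#' falls below \code{score_floor} are flagged for review.
#'
#' @param reference_mask logical ROI mask valid for \code{reference_frame}.
#' @param reference_frame structural-channel reference image.
#' @param movie \code{[h, w, T]} structural-channel array (or a
#'   [TwoChannelMovie-class], whose structural channel is used).
#' @param search_radius maximum shift searched (px, default 10).
#' @param margin patch margin around the mask bounding box (default 2).
#' @param score_floor QC flag threshold on the correlation score.
#' @return list with \code{masks} (per-frame logical masks), \code{shifts}
#'   (\code{T x 2} row/col shifts), \code{scores}, \code{flagged} (logical).
#' @export
trackRoi <- function(reference_mask, reference_frame, movie,
                     search_radius = 10, margin = 2, score_floor = 0.5) {
  arr <- if (is(movie, "TwoChannelMovie")) structuralChannel(movie) else movie
  h <- nrow(reference_frame); w <- ncol(reference_frame)
  stopifnot(identical(dim(reference_mask), dim(reference_frame)),
            identical(dim(arr)[1:2], dim(reference_frame)))
  idx <- which(reference_mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty reference mask")
  r0 <- max(1, min(idx[, 1]) - margin); r1 <- min(h, max(idx[, 1]) + margin)
  c0 <- max(1, min(idx[, 2]) - margin); c1 <- min(w, max(idx[, 2]) + margin)
  P <- reference_frame[r0:r1, c0:c1]
  P <- P - mean(P); np <- sqrt(sum(P^2))
  nT <- dim(arr)[3]
  sr <- search_radius
  # clip the search window so shifted patches stay inside the image
  lo1 <- -min(sr, r0 - 1); hi1 <- min(sr, h - r1)
  lo2 <- -min(sr, c0 - 1); hi2 <- min(sr, w - c1)
  if (lo1 > -sr || hi1 < sr || lo2 > -sr || hi2 < sr)
    warning("search window clipped at the image border")
  shifts <- matrix(0L, nT, 2); scores <- numeric(nT)
  masks <- vector("list", nT)
  # precompute, for every candidate shift, the linear indices of the
  # shifted patch within the search block so each frame needs one gather
  ph <- r1 - r0 + 1; pw <- c1 - c0 + 1
  bh <- ph + hi1 - lo1; bw <- pw + hi2 - lo2
  sh <- as.matrix(expand.grid(d1 = lo1:hi1, d2 = lo2:hi2))
  pRel <- as.matrix(expand.grid(pr = seq_len(ph), pc = seq_len(pw)))
  m <- nrow(pRel)
  idxMat <- matrix(0L, m, nrow(sh))
  for (s in seq_len(nrow(sh))) {
    rr <- pRel[, 1] + (sh[s, 1] - lo1)
    cc <- pRel[, 2] + (sh[s, 2] - lo2)
    idxMat[, s] <- (cc - 1L) * bh + rr
  }
  Pv <- as.vector(P)
  for (t in seq_len(nT)) {
    B <- arr[(r0 + lo1):(r1 + hi1), (c0 + lo2):(c1 + hi2), t]
    Qm <- matrix(B[idxMat], m, nrow(sh))
    qMean <- colMeans(Qm)
    num <- as.vector(crossprod(Qm, Pv))           # P is already centered
    den <- sqrt(pmax(colSums(Qm^2) - m * qMean^2, 0)) * np
    sc <- ifelse(den > 0, num / den, -Inf)
    s <- which.max(sc)
    b1 <- sh[s, 1]; b2 <- sh[s, 2]
    shifts[t, ] <- c(b1, b2); scores[t] <- sc[s]
    mm <- matrix(FALSE, h, w)
    nr <- idx[, 1] + b1; nc <- idx[, 2] + b2
    ok <- nr >= 1 & nr <= h & nc >= 1 & nc <= w
    mm[cbind(nr[ok], nc[ok])] <- TRUE
    masks[[t]] <- mm
  }
  list(masks = masks, shifts = shifts, scores = scores,
       flagged = scores < score_floor)
}

#' Rasterize an elliptical ROI
#'
#' Stand-in for manually positioned elliptical ROIs of arbitrary
#' orientation, used when erosion-based detection yields malformed ROIs.
#'
#' @param center \code{c(row, col)}.
#' @param axes \code{c(a, b)} semi-axes in px (both > 0).
#' @param angle orientation in degrees (first axis relative to the row
#'   direction).
#' @param frame_shape \code{c(h, w)}.
#' @return logical mask.
#' @export
ellipticalRoi <- function(center, axes, angle, frame_shape) {
  if (any(axes <= 0)) stop("degenerate ellipse axis")
  h <- frame_shape[1]; w <- frame_shape[2]
  if (center[1] - max(axes) < 1 || center[1] + max(axes) > h ||
      center[2] - max(axes) < 1 || center[2] + max(axes) > w)
    stop("ellipse out of frame bounds")
  g <- coordGrid(h, w)
  th <- angle * pi / 180
  dr <- g$r - center[1]; dc <- g$c - center[2]
  a1 <- dr * cos(th) + dc * sin(th)
  a2 <- -dr * sin(th) + dc * cos(th)
  (a1 / axes[1])^2 + (a2 / axes[2])^2 <= 1
}

#' Extract a ratiometric (%dR/R) trace from a tracked ROI
#'
#' Per frame, the ratio R_t is the mean activity-channel intensity over the
#' mask divided by the mean structural-channel intensity; shared per-frame
#' intensity fluctuations (motion) cancel in the ratio. In the absence of
#' stimuli, the baseline R0 is the minimum ratio within a 2.5 s bin: the
#' trace is averaged in non-overlapping bins of \code{baseline_bin_s} and
#' R0 is the smallest bin mean. The reported signal is
#' \code{100 * (R_t - R0) / R0}.
#'
#' @param movie a [TwoChannelMovie-class].
#' @param masks per-frame list of logical masks (from [trackRoi()]), or one
#'   mask applied to every frame.
#' @param baseline_bin_s baseline bin width in seconds (default 2.5).
#' @param roi_label optional label stored on the result.
#' @return data.frame of class \code{"RatioTrace"} with columns \code{t},
#'   \code{percent_dRR} and attribute \code{"roi_label"}.
#' @export
extractRatioTrace <- function(movie, masks, baseline_bin_s = 2.5,
                              roi_label = "roi") {
  stopifnot(is(movie, "TwoChannelMovie"))
  nT <- nFrames(movie)
  if (is.matrix(masks) || is.logical(masks)) masks <- rep(list(masks), nT)
  stopifnot(length(masks) == nT)
  act <- activityChannel(movie); str <- structuralChannel(movie)
  R <- numeric(nT)
  for (t in seq_len(nT)) {
    m <- masks[[t]]
    sden <- mean(str[, , t][m])
    if (!is.finite(sden) || sden <= 0) {
      warning("non-positive structural mean at frame ", t, "; sample masked")
      R[t] <- NA
      next
    }
    R[t] <- mean(act[, , t][m]) / sden
  }
  t <- frameTimes(movie)
  bins <- floor(t / baseline_bin_s)
  binMeans <- tapply(R, bins, mean, na.rm = TRUE)
  R0 <- min(binMeans, na.rm = TRUE)
  if (!is.finite(R0) || R0 <= 0) stop("non-positive baseline ratio")
  out <- data.frame(t = t, percent_dRR = 100 * (R - R0) / R0)
  attr(out, "roi_label") <- roi_label
  class(out) <- c("RatioTrace", "data.frame")
  out
}

#' Left/right covariance of ratiometric traces
#'
#' Pearson correlation of the left- and right-neuron %dR/R traces; used to
#' decide whether a bilateral pair covaries (and hence which reconciliation
#' rule applies during event detection).
#'
#' @param trace_L,trace_R numeric vectors or \code{RatioTrace} data.frames
#'   of equal length (at least 3 samples).
#' @return Pearson's r.
#' @export
leftRightCovariance <- function(trace_L, trace_R) {
  xl <- if (is.data.frame(trace_L)) trace_L$percent_dRR else trace_L
  xr <- if (is.data.frame(trace_R)) trace_R$percent_dRR else trace_R
  if (length(xl) != length(xr) || length(xl) < 3)
    stop("traces must have equal length >= 3")
  if (stats::sd(xl) == 0 || stats::sd(xr) == 0)
    stop("zero variance: correlation undefined")
  stats::cor(xl, xr)
}
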
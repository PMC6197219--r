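# Behavior quantification: treadmill optic flow to calibrated velocities,
# locomotor bout segmentation, and walking/grooming annotation from video.

# Calibration for a 10 mm treadmill ball: one ball rotation per second is
# 31.42 mm/s of translation and 360 deg/s of yaw.
.MM_PER_ROT <- 31.42
.DEG_PER_ROT <- 360

#' Resample timestamped signals to a common timebase
#'
#' Data acquisition rates differ across optic flow, videography and 2-photon
#' imaging; all signals are linearly interpolated onto the timestamp grid of
#' the highest-rate signal, restricted to the common time overlap.
#'
#' @param signals list of data.frames, each with a \code{t} column and one or
#'   more value columns.
#' @return list of data.frames on the shared grid.
#' @export
resampleToCommonTimebase <- function(signals) {
  stopifnot(length(signals) >= 1)
  for (s in signals)
    if (!is.data.frame(s) || !"t" %in% names(s) || nrow(s) < 2)
      stop("each signal needs a 't' column and at least 2 samples")
  if (length(signals) == 1) return(signals)
  lo <- max(vapply(signals, function(s) min(s$t), numeric(1)))
  hi <- min(vapply(signals, function(s) max(s$t), numeric(1)))
  if (lo >= hi) stop("signals have disjoint time support")
  rates <- vapply(signals, function(s) (nrow(s) - 1) / diff(range(s$t)),
                  numeric(1))
  master <- signals[[which.max(rates)]]
  grid <- master$t[master$t >= lo & master$t <= hi]
  lapply(signals, function(s) {
    out <- data.frame(t = grid)
    for (v in setdiff(names(s), "t")) out[[v]] <- interp1(s$t, s[[v]], grid)
    out
  })
}

#' Convert raw optic flow to calibrated velocities
#'
#' Smooths each axis with a centered running average (window truncated at
#' the trace edges), then converts rotations/s to mm/s for the
#' anterior-posterior and medial-lateral axes and to deg/s for yaw.
#'
#' @param raw data.frame with columns \code{t, ap, ml, yaw} (rotations/s).
#' @param smoothing_window running-average window in seconds (default 0.2).
#' @return data.frame with columns \code{t, v_forward, v_side, v_rotation}.
#' @export
convertOpticFlow <- function(raw, smoothing_window = 0.2) {
  stopifnot(all(c("t", "ap", "ml", "yaw") %in% names(raw)))
  if (is.unsorted(raw$t, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  dt <- stats::median(diff(raw$t))
  k <- floor(smoothing_window / (2 * dt))
  if (smoothing_window < dt) {
    warning("smoothing window shorter than one sample interval; no smoothing")
    k <- 0
  }
  data.frame(t = raw$t,
             v_forward = .MM_PER_ROT * runningMeanCentered(raw$ap, k),
             v_side = .MM_PER_ROT * runningMeanCentered(raw$ml, k),
             v_rotation = .DEG_PER_ROT * runningMeanCentered(raw$yaw, k))
}

# Maximal constant-label runs of `labels` at timestamps `t`, excluding
# `exclude` labels; returns data.frame(label, start, end).
labelRuns <- function(labels, t, exclude = character(0)) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- !(r$values %in% exclude)
  dt <- if (length(t) > 1) stats::median(diff(t)) else 0
  data.frame(label = r$values[keep], start = t[starts[keep]],
             end = t[ends[keep]] + dt)
}

#' Segment locomotor bouts from a velocity trace
#'
#' The forward-velocity trace is resampled to \code{downsample_rate} and
#' smoothed with a running average; samples above \code{+walk_threshold}
#' are forward walking, below \code{-walk_threshold} backward walking, and
#' in between standing still. Turning is classified independently at
#' \code{+/-turn_threshold} on the rotational velocity (cw positive, ccw
#' negative). A bout is a maximal run of a constant non-still label.
#'
#' @param vel data.frame from [convertOpticFlow()].
#' @param walk_threshold mm/s (default 0.31).
#' @param turn_threshold deg/s (default 10.8).
#' @param downsample_rate samples/s for classification (default 1500).
#' @param smooth_s running-average duration in seconds (default 0.2).
#' @return list of class \code{"BoutSegmentation"}: \code{t},
#'   \code{walk_labels}, \code{turn_labels}, \code{bouts},
#'   \code{percent_time_walking}.
#' @export
segmentBouts <- function(vel, walk_threshold = 0.31, turn_threshold = 10.8,
                         downsample_rate = 1500, smooth_s = 0.2) {
  if (!nrow(vel)) stop("empty velocity trace")
  grid <- seq(min(vel$t), max(vel$t), by = 1 / downsample_rate)
  vf <- interp1(vel$t, vel$v_forward, grid)
  vr <- interp1(vel$t, vel$v_rotation, grid)
  k <- floor(smooth_s * downsample_rate / 2)
  vf <- runningMeanCentered(vf, k)
  vr <- runningMeanCentered(vr, k)
  walk <- ifelse(vf > walk_threshold, "forward",
                 ifelse(vf < -walk_threshold, "backward", "still"))
  turn <- ifelse(vr > turn_threshold, "cw",
                 ifelse(vr < -turn_threshold, "ccw", "none"))
  bouts <- rbind(labelRuns(walk, grid, exclude = "still"),
                 labelRuns(turn, grid, exclude = "none"))
  structure(list(t = grid, walk_labels = walk, turn_labels = turn,
                 bouts = bouts,
                 percent_time_walking = 100 * mean(walk != "still")),
            class = "BoutSegmentation")
}

#' Annotation parameters for behavior video
#'
#' @param roi_walk,roi_groom rectangles \code{c(row0, row1, col0, col1)}:
#'   the walking ROI over the meta-/mesothoracic legs and the grooming ROI
#'   in front of the fly. They may not overlap.
#' @param blur_radius median-blur radius in pixels (default 5).
#' @param threshold_walk minimum count of non-zero blurred-difference pixels
#'   in the walk ROI (default 400).
#' @param threshold_groom same for the groom ROI (default 5).
#' @param hysteresis_walk minimum run length, in frames, for a walking state
#'   (default 8).
#' @param hysteresis_groom same for grooming (default 10).
#' @return validated list of class \code{"AnnotationParams"}.
#' @export
annotationParams <- function(roi_walk, roi_groom, blur_radius = 5,
                             threshold_walk = 400, threshold_groom = 5,
                             hysteresis_walk = 8, hysteresis_groom = 10) {
  stopifnot(length(roi_walk) == 4, length(roi_groom) == 4,
            threshold_walk >= 0, threshold_groom >= 0)
  if (roi_walk[1] > roi_walk[2] || roi_walk[3] > roi_walk[4] ||
      roi_groom[1] > roi_groom[2] || roi_groom[3] > roi_groom[4])
    stop("ROI rectangles must be c(row0, row1, col0, col1) with row0 <= row1")
  overlap <- !(roi_walk[2] < roi_groom[1] || roi_groom[2] < roi_walk[1] ||
               roi_walk[4] < roi_groom[3] || roi_groom[4] < roi_walk[3])
  if (overlap) stop("walk and groom ROIs may not overlap")
  structure(list(roi_walk = roi_walk, roi_groom = roi_groom,
                 blur_radius = blur_radius, threshold_walk = threshold_walk,
                 threshold_groom = threshold_groom,
                 hysteresis_walk = hysteresis_walk,
                 hysteresis_groom = hysteresis_groom),
            class = "AnnotationParams")
}

#' Minimum-run-length (hysteresis) filter for a binary sequence
#'
#' Suppresses any run of constant value shorter than \code{min_run} frames
#' by absorbing it into the surrounding state, repeating until no short run
#' remains; idempotent by construction.
#'
#' @param x binary (0/1) vector.
#' @param min_run minimum admissible run length in frames.
#' @return filtered binary vector.
#' @export
hysteresisFilter <- function(x, min_run) {
  if (min_run <= 1 || length(x) < 2) return(x)
  repeat {
    r <- rle(x)
    if (length(r$lengths) == 1) return(x)
    short <- which(r$lengths < min_run)
    if (!length(short)) return(x)
    # flip the shortest run first; re-run until stable
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    idx <- (ends[k] - r$lengths[k] + 1):ends[k]
    x[idx] <- 1 - r$values[k]
  }
}

#' Annotate walking and grooming from behavior video
#'
#' Consecutive frames are subtracted; absolute difference images are median
#' blurred to reduce noise; the count of non-zero pixels in each ROI is
#' thresholded to give binary walking and grooming sequences. Prothoracic
#' leg movements during walking are ignored (grooming is subservient to
#' walking). A hysteresis filter removes runs too short to be biologically
#' plausible.
#'
#' @param frames \code{[h, w, T]} array of grayscale frames.
#' @param params an [annotationParams()].
#' @return list of class \code{"BehaviorAnnotation"}: binary vectors
#'   \code{S_w}, \code{S_g} of length \code{T - 1} (one per frame pair) and
#'   the per-ROI difference pixel counts.
#' @export
annotateVideo <- function(frames, params) {
  stopifnot(inherits(params, "AnnotationParams"))
  d <- dim(frames)
  if (length(d) != 3 || d[3] < 2) stop("need at least 2 frames")
  rw <- params$roi_walk; rg <- params$roi_groom
  if (rw[1] < 1 || rw[2] > d[1] || rw[3] < 1 || rw[4] > d[2] ||
      rg[1] < 1 || rg[2] > d[1] || rg[3] < 1 || rg[4] > d[2])
    stop("ROI outside frame bounds")
  nT <- d[3] - 1
  cw <- numeric(nT); cg <- numeric(nT)
  scale <- max(abs(frames))
  if (scale == 0) scale <- 1
  for (k in seq_len(nT)) {
    df <- abs(frames[, , k + 1] - frames[, , k]) / scale
    if (max(df) > 0)
      df <- as.matrix(EBImage::medianFilter(df, params$blur_radius))
    cw[k] <- sum(df[rw[1]:rw[2], rw[3]:rw[4]] > 1e-9)
    cg[k] <- sum(df[rg[1]:rg[2], rg[3]:rg[4]] > 1e-9)
  }
  Sw <- as.integer(cw >= params$threshold_walk)
  Sw <- hysteresisFilter(Sw, params$hysteresis_walk)
  Sg <- as.integer(cg >= params$threshold_groom & Sw == 0L)
  Sg <- hysteresisFilter(Sg, params$hysteresis_groom)
  Sg[Sw == 1L] <- 0L
  structure(list(S_w = Sw, S_g = Sg, count_walk = cw, count_groom = cg),
            class = "BehaviorAnnotation")
}
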
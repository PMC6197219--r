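# Synthetic two-photon experiments with known ground truth.
#
# Every downstream stage (registration, behavior quantification, regression
# maps, ROI signals, event detection) is exercised against data produced
# here, where the deformation fields, planted transients and behavior
# schedule are known exactly.

.validStates <- c("still", "walk_fwd", "walk_bwd", "turn_left", "turn_right",
                  "groom", "push_down")
.walkStates <- c("walk_fwd", "walk_bwd", "turn_left", "turn_right")

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the acquisition conditions of the real preparation:
#' Galvo-Galvo coronal/horizontal imaging at ~8 Hz, ~30 fps behavior video,
#' treadmill optic-flow sensors sampled well above the imaging rate, and a
#' GCaMP6s decay half-life of 1.1448 s.
#'
#' @param image_height,image_width image size in pixels.
#' @param n_frames number of 2-photon frames.
#' @param frame_rate 2-photon frame rate (Hz).
#' @param deformation_amplitude maximum displacement magnitude (px).
#' @param deformation_smoothness spatial correlation scale of the fields (px).
#' @param noise_sd additive Gaussian noise SD on both channels
#'   (intensity units; the template has unit dynamic range).
#' @param gain multiplicative activity gain: active pixels scale the
#'   structural template by \code{1 + gain * a(t)}.
#' @param event_times named list of per-neuron onset times (s), e.g.
#'   \code{list(left = c(12, 30), right = c(12.4))}.
#' @param cir_half_life calcium-indicator decay half-life (s).
#' @param behavior_schedule data.frame with columns \code{state}
#'   (one of still, walk_fwd, walk_bwd, turn_left, turn_right, groom,
#'   push_down), \code{start}, \code{end} (s); non-overlapping, within the
#'   recording.
#' @param flow_rate optic-flow sample rate (Hz).
#' @param flow_noise_sd optic-flow sensor noise SD (rot/s).
#' @param walk_speed_rot forward-walking ball speed (rot/s).
#' @param video_fps behavior-video frame rate (Hz).
#' @param video_height,video_width behavior-video frame size.
#' @param n_blobs number of bright blobs in the structural template.
#' @param rng_seed integer seed; all generators are deterministic given it.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @examples
#' cfg <- syntheticConfig(n_frames = 20, rng_seed = 1)
#' @export
syntheticConfig <- function(image_height = 64, image_width = 64,
                            n_frames = 100, frame_rate = 8,
                            deformation_amplitude = 3,
                            deformation_smoothness = 12,
                            noise_sd = 0.01, gain = 1,
                            event_times = list(left = numeric(0),
                                               right = numeric(0)),
                            cir_half_life = 1.1448,
                            behavior_schedule = data.frame(
                              state = character(0), start = numeric(0),
                              end = numeric(0)),
                            flow_rate = 200, flow_noise_sd = 0,
                            walk_speed_rot = 0.5,
                            video_fps = 30, video_height = 96,
                            video_width = 96,
                            n_blobs = 20, rng_seed = 1) {
  if (image_height < 8 || image_width < 8)
    stop("invalid dimensions: images must be at least 8 x 8")
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (deformation_amplitude < 0) stop("deformation_amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  sched <- behavior_schedule
  duration <- n_frames / frame_rate
  if (nrow(sched)) {
    if (!all(sched$state %in% .validStates))
      stop("unknown behavior state label: ",
           paste(setdiff(sched$state, .validStates), collapse = ", "))
    if (any(sched$start >= sched$end))
      stop("behavior_schedule intervals must have start < end")
    if (any(sched$start < 0) || any(sched$end > duration))
      stop("behavior_schedule must lie within [0, n_frames/frame_rate)")
    o <- order(sched$start)
    sched <- sched[o, , drop = FALSE]
    if (nrow(sched) > 1 &&
        any(sched$start[-1] < sched$end[-nrow(sched)]))
      stop("behavior_schedule intervals must be non-overlapping")
  }
  structure(list(
    image_height = image_height, image_width = image_width,
    n_frames = n_frames, frame_rate = frame_rate,
    deformation_amplitude = deformation_amplitude,
    deformation_smoothness = deformation_smoothness,
    noise_sd = noise_sd, gain = gain, event_times = event_times,
    cir_half_life = cir_half_life, behavior_schedule = sched,
    flow_rate = flow_rate, flow_noise_sd = flow_noise_sd,
    walk_speed_rot = walk_speed_rot, video_fps = video_fps,
    video_height = video_height, video_width = video_width,
    n_blobs = n_blobs, rng_seed = as.integer(rng_seed),
    duration = duration), class = "SyntheticConfig")
}

# Behavior state at each timestamp, from the schedule ("still" outside).
scheduleStates <- function(schedule, times) {
  states <- rep("still", length(times))
  for (i in seq_len(nrow(schedule)))
    states[times >= schedule$start[i] & times < schedule$end[i]] <-
      schedule$state[i]
  states
}

#' Structural-channel template image
#'
#' Sparse bright blobs (neurite cross-sections) on a dim textured background,
#' with enough gradient content everywhere for feature matching.
#'
#' @param config a [syntheticConfig()].
#' @return nonnegative numeric matrix, deterministic given the seed.
#' @export
makeStructuralTemplate <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  h <- config$image_height; w <- config$image_width
  set.seed(config$rng_seed)
  img <- matrix(0.1, h, w)
  g <- coordGrid(h, w)
  for (i in seq_len(config$n_blobs)) {
    cr <- stats::runif(1, 4, h - 3); cc <- stats::runif(1, 4, w - 3)
    amp <- stats::runif(1, 0.4, 1); sg <- stats::runif(1, 1.2, 2.5)
    img <- img + amp * exp(-((g$r - cr)^2 + (g$c - cc)^2) / (2 * sg^2))
  }
  # broad low-frequency texture so no region is featureless
  tex <- matrix(stats::rnorm(h * w), h, w)
  tex <- as.matrix(EBImage::gblur(tex, sigma = 4))
  img <- img + 0.08 * (tex - min(tex))
  pmax(img, 0)
}

#' Per-frame smooth non-rigid deformation fields
#'
#' Spatially low-pass-filtered independent random displacement components,
#' temporally smoothed by a short moving average, rescaled so the maximum
#' displacement magnitude over the whole sequence equals
#' \code{deformation_amplitude}. The field for frame 1 is identically zero
#' (frame 1 is the registration reference).
#'
#' @param config a [syntheticConfig()].
#' @return list of \code{[h, w, 2]} arrays, one per frame.
#' @export
makeDeformationSequence <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (config$deformation_amplitude < 0)
    stop("deformation_amplitude must be >= 0")
  h <- config$image_height; w <- config$image_width; nT <- config$n_frames
  zero <- array(0, c(h, w, 2))
  if (config$deformation_amplitude == 0)
    return(rep(list(zero), nT))
  set.seed(config$rng_seed + 1L)
  raw <- array(stats::rnorm(h * w * 2 * nT), c(h, w, 2, nT))
  for (t in seq_len(nT)) for (k in 1:2)
    raw[, , k, t] <- gaussianSmoothFFT(raw[, , k, t],
                                       config$deformation_smoothness)
  # temporal moving average (window 3), then anchor frame 1 at zero
  sm <- raw
  for (t in seq_len(nT)) {
    idx <- max(1, t - 1):min(nT, t + 1)
    sm[, , , t] <- apply(raw[, , , idx, drop = FALSE], 1:3, mean)
  }
  for (t in nT:1) sm[, , , t] <- sm[, , , t] - sm[, , , 1]
  mag <- sqrt(sm[, , 1, ]^2 + sm[, , 2, ]^2)
  mx <- max(mag)
  scale <- if (mx > 0) config$deformation_amplitude / mx else 0
  lapply(seq_len(nT), function(t) {
    f <- array(0, c(h, w, 2)); f[, , 1] <- sm[, , 1, t] * scale
    f[, , 2] <- sm[, , 2, t] * scale; f
  })
}

# Approximate inverse of a motion field by fixed-point iteration:
# u(y) = -w(y + u(y)). Used to render frames whose *registration* field
# (mapping reference coordinates to frame coordinates) is exactly `field`.
invertField <- function(field, iters = 6) {
  h <- dim(field)[1]; w <- dim(field)[2]
  g <- coordGrid(h, w)
  u1 <- -field[, , 1]; u2 <- -field[, , 2]
  for (k in seq_len(iters)) {
    r <- as.vector(g$r + u1); c <- as.vector(g$c + u2)
    u1 <- -matrix(bilinearSample(field[, , 1], r, c), h, w)
    u2 <- -matrix(bilinearSample(field[, , 2], r, c), h, w)
  }
  out <- array(0, c(h, w, 2)); out[, , 1] <- u1; out[, , 2] <- u2
  out
}

# Peak-normalized causal exponential transient train at times `t`.
eventTrain <- function(onsets, t, half_life) {
  a <- numeric(length(t))
  for (on in onsets) {
    act <- t >= on
    a[act] <- a[act] + exp(-log(2) * (t[act] - on) / half_life)
  }
  a
}

#' Ground truth for a synthetic experiment
#'
#' Builds the activity sources (left/right neuron disks with planted event
#' trains; walking- and grooming-coupled pixel regions driven by the
#' behavior schedule), the per-frame behavior states, and placeholders for
#' the true deformation fields.
#'
#' @param config a [syntheticConfig()].
#' @param fields optional list of true motion fields
#'   (from [makeDeformationSequence()]); zero fields if omitted.
#' @return list of class \code{"GroundTruth"} with elements
#'   \code{true_fields}, \code{true_event_onsets}, \code{masks} (named binary
#'   matrices: left, right, walking, grooming), \code{activity} (matrix
#'   \code{[T, source]} of unit-scale activity traces at frame times),
#'   \code{behavior_states}, \code{schedule}.
#' @export
makeGroundTruth <- function(config, fields = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  h <- config$image_height; w <- config$image_width
  if (is.null(fields))
    fields <- rep(list(array(0, c(h, w, 2))), config$n_frames)
  g <- coordGrid(h, w)
  disk <- function(cr, cc, rad) (g$r - cr)^2 + (g$c - cc)^2 <= rad^2
  masks <- list(
    left  = disk(h * 0.50, w * 0.25, 4),
    right = disk(h * 0.50, w * 0.75, 4),
    walking  = disk(h * 0.25, w * 0.30, 5) | disk(h * 0.22, w * 0.62, 4),
    grooming = disk(h * 0.78, w * 0.40, 5) | disk(h * 0.75, w * 0.70, 4))
  t <- (seq_len(config$n_frames) - 1) / config$frame_rate
  states <- scheduleStates(config$behavior_schedule, t)
  kern <- exp(-log(2) * (0:ceiling(5 * config$cir_half_life *
              config$frame_rate)) / (config$cir_half_life * config$frame_rate))
  convNorm <- function(s) {
    x <- stats::convolve(s, rev(kern), type = "open")[seq_along(s)]
    if (max(x) > 0) x / max(x) else x
  }
  activity <- cbind(
    left  = eventTrain(config$event_times$left %||% numeric(0), t,
                       config$cir_half_life),
    right = eventTrain(config$event_times$right %||% numeric(0), t,
                       config$cir_half_life),
    walking  = convNorm(as.numeric(states %in% .walkStates)),
    grooming = convNorm(as.numeric(states == "groom")))
  structure(list(true_fields = fields,
                 true_event_onsets = config$event_times,
                 masks = masks, activity = activity,
                 behavior_states = states,
                 schedule = config$behavior_schedule),
            class = "GroundTruth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a two-channel movie from template, fields and ground truth
#'
#' The structural channel is the template deformed frame-to-frame so that the
#' field registering frame \code{t} back to the reference is exactly
#' \code{ground_truth$true_fields[[t]]} (up to interpolation error), plus
#' noise. The activity channel is the template scaled per pixel by
#' \code{1 + gain * sum(a_src(t) * mask_src)} before the identical
#' deformation, so the structural channel stays activity-independent.
#'
#' @param template structural template image.
#' @param fields list of true motion fields (reference -> frame).
#' @param ground_truth a [makeGroundTruth()] result.
#' @param config the [syntheticConfig()].
#' @return A [TwoChannelMovie-class].
#' @export
renderMovie <- function(template, fields, ground_truth, config) {
  stopifnot(inherits(config, "SyntheticConfig"),
            inherits(ground_truth, "GroundTruth"))
  h <- nrow(template); w <- ncol(template); nT <- config$n_frames
  if (length(fields) != nT)
    stop("fields length must equal n_frames")
  for (m in ground_truth$masks)
    if (!identical(dim(m), dim(template))) stop("mask shape mismatch")
  act <- array(0, c(h, w, nT)); str <- array(0, c(h, w, nT))
  A <- ground_truth$activity
  set.seed(config$rng_seed + 2L)
  for (t in seq_len(nT)) {
    gmap <- matrix(1, h, w)
    for (nm in colnames(A))
      gmap <- gmap + config$gain * A[t, nm] * ground_truth$masks[[nm]]
    if (max(abs(fields[[t]])) == 0) {
      sf <- template
      af <- template * gmap
    } else {
      u <- invertField(fields[[t]])
      sf <- warpFrame(template, u)
      af <- warpFrame(template * gmap, u)
    }
    if (config$noise_sd > 0) {
      sf <- sf + matrix(stats::rnorm(h * w, sd = config$noise_sd), h, w)
      af <- af + matrix(stats::rnorm(h * w, sd = config$noise_sd), h, w)
    }
    str[, , t] <- sf; act[, , t] <- af
  }
  TwoChannelMovie(act, str, config$frame_rate)
}

#' Synthetic spherical-treadmill optic-flow traces
#'
#' Raw two-sensor optic flow in rotations/s for the anterior-posterior,
#' medial-lateral and yaw axes, coupled to the behavior schedule: forward
#' walking gives positive AP flow, backward walking negative AP flow,
#' turning gives signed yaw (left negative) with matching medial-lateral
#' flow, and push-down gives a biphasic AP pulse.
#'
#' @param ground_truth a [makeGroundTruth()] result.
#' @param config the [syntheticConfig()].
#' @return data.frame with columns \code{t, ap, ml, yaw} at
#'   \code{config$flow_rate} Hz.
#' @export
makeOpticFlow <- function(ground_truth, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  t <- seq(0, config$duration - 1 / config$flow_rate, by = 1 / config$flow_rate)
  ap <- ml <- yaw <- numeric(length(t))
  sched <- config$behavior_schedule
  for (i in seq_len(nrow(sched))) {
    idx <- t >= sched$start[i] & t < sched$end[i]
    dur <- sched$end[i] - sched$start[i]
    switch(sched$state[i],
      walk_fwd  = { ap[idx] <- config$walk_speed_rot },
      walk_bwd  = { ap[idx] <- -0.3 },
      turn_left = { yaw[idx] <- -0.5; ml[idx] <- -0.2 },
      turn_right = { yaw[idx] <- 0.5; ml[idx] <- 0.2 },
      push_down = { ap[idx] <- 0.8 * sin(2 * pi * (t[idx] - sched$start[i]) / dur) },
      groom = NULL, still = NULL,
      stop("unknown state label: ", sched$state[i]))
  }
  if (config$flow_noise_sd > 0) {
    set.seed(config$rng_seed + 3L)
    n <- length(t)
    ap <- ap + stats::rnorm(n, sd = config$flow_noise_sd)
    ml <- ml + stats::rnorm(n, sd = config$flow_noise_sd)
    yaw <- yaw + stats::rnorm(n, sd = config$flow_noise_sd)
  }
  data.frame(t = t, ap = ap, ml = ml, yaw = yaw)
}

#' Synthetic behavior-video frames
#'
#' Grayscale frames with a rear-legs region whose texture changes every
#' frame during walking states and a front region that moves during
#' grooming; everything is static otherwise. The two regions match the
#' default annotation ROIs returned in the result.
#'
#' @param ground_truth a [makeGroundTruth()] result.
#' @param config the [syntheticConfig()].
#' @return list with \code{frames} (\code{[h, w, T]} array in [0, 1]),
#'   \code{fps}, \code{times}, \code{states} (per frame), and rectangles
#'   \code{roi_walk}, \code{roi_groom} as \code{c(row0, row1, col0, col1)}.
#' @export
makeBehaviorFrames <- function(ground_truth, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  h <- config$video_height; w <- config$video_width
  times <- seq(0, config$duration - 1 / config$video_fps,
               by = 1 / config$video_fps)
  states <- scheduleStates(config$behavior_schedule, times)
  roiWalk <- c(round(h * 0.55), h - 4, 5, w - 5)
  roiGroom <- c(5, round(h * 0.30), round(w * 0.30), round(w * 0.70))
  set.seed(config$rng_seed + 4L)
  base <- matrix(stats::runif(h * w, 0, 0.3), h, w)
  frames <- array(0, c(h, w, length(times)))
  rw <- roiWalk[1]:roiWalk[2]; cw <- roiWalk[3]:roiWalk[4]
  rg <- roiGroom[1]:roiGroom[2]; cg <- roiGroom[3]:roiGroom[4]
  cur <- base
  for (k in seq_along(times)) {
    if (states[k] %in% .walkStates)
      cur[rw, cw] <- matrix(stats::rbinom(length(rw) * length(cw), 1, 0.5),
                            length(rw), length(cw))
    if (states[k] == "groom")
      cur[rg, cg] <- matrix(stats::rbinom(length(rg) * length(cg), 1, 0.5),
                            length(rg), length(cg))
    frames[, , k] <- cur
  }
  list(frames = frames, fps = config$video_fps, times = times,
       states = states, roi_walk = roiWalk, roi_groom = roiGroom)
}

#' Generate a complete synthetic experiment
#'
#' Convenience driver chaining template, deformation fields, ground truth,
#' movie rendering, optic flow and behavior video.
#'
#' @param config a [syntheticConfig()].
#' @return list with \code{config, template, ground_truth, movie, flow,
#'   video}.
#' @export
generateSyntheticExperiment <- function(config = syntheticConfig()) {
  template <- makeStructuralTemplate(config)
  fields <- makeDeformationSequence(config)
  gt <- makeGroundTruth(config, fields)
  movie <- renderMovie(template, fields, gt, config)
  flow <- makeOpticFlow(gt, config)
  video <- makeBehaviorFrames(gt, config)
  list(config = config, template = template, ground_truth = gt,
       movie = movie, flow = flow, video = video)
}
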
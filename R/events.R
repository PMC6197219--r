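# Fluorescence transient event detection, bilateral reconciliation, and
# event-triggered summaries with bootstrapped confidence intervals and
# time-shuffled controls.

#' Event-detection configuration
#'
#' @param percentile derivative-threshold percentile over the pooled
#'   derivative values of a neuron class: 97.5 for MDN/dMAN-like classes,
#'   90 for A1-like classes with many more transients.
#' @param covarying_pair TRUE for strongly covarying bilateral pairs
#'   (MDN, dMAN): unilateral events are copied to the partner. FALSE for
#'   independent pairs (A1): near-coincident bilateral events are vetoed.
#' @param pair_merge_window seconds within which covarying-pair events are
#'   considered the same event (default 2).
#' @param independent_veto_window seconds within which independent-pair
#'   events are discarded on both sides (default 0.25).
#' @param edge_exclusion seconds excluded at both ends of each experiment
#'   (default 10, matching the presentation window).
#' @param summary_window half-width of the event-triggered window (s).
#' @param summary_rate resampling rate for summaries (samples/s).
#' @param n_bootstrap bootstrap replicates for the 95% CI.
#' @return validated list of class \code{"EventConfig"}.
#' @export
eventConfig <- function(percentile = 97.5, covarying_pair = TRUE,
                        pair_merge_window = 2, independent_veto_window = 0.25,
                        edge_exclusion = 10, summary_window = 10,
                        summary_rate = 500, n_bootstrap = 1000) {
  stopifnot(percentile > 0, percentile < 100, pair_merge_window > 0,
            independent_veto_window > 0, edge_exclusion >= 0,
            summary_window > 0, summary_rate > 0, n_bootstrap >= 1)
  structure(list(percentile = percentile, covarying_pair = covarying_pair,
                 pair_merge_window = pair_merge_window,
                 independent_veto_window = independent_veto_window,
                 edge_exclusion = edge_exclusion,
                 summary_window = summary_window,
                 summary_rate = summary_rate, n_bootstrap = n_bootstrap),
            class = "EventConfig")
}

# First difference scaled by the sample interval; one value per interval,
# indexed at the left sample.
traceDerivative <- function(trace) {
  diff(trace$percent_dRR) / diff(trace$t)
}

#' Pooled derivative threshold for a neuron class
#'
#' Fluorescence dynamics are characteristic of a neuron class, not of a
#' single experiment, so the detection threshold is a percentile of the
#' first-derivative values pooled over all traces of the class (across
#' experiments and animals). Percentiles interpolate linearly between order
#' statistics.
#'
#' @param traces list of \code{RatioTrace} data.frames (or one data.frame).
#' @param percentile percentile in (0, 100).
#' @return scalar threshold (%dR/R per second).
#' @export
poolDerivativeThreshold <- function(traces, percentile) {
  if (is.data.frame(traces)) traces <- list(traces)
  if (!length(traces)) stop("empty trace pool")
  pooled <- unlist(lapply(traces, traceDerivative))
  unname(stats::quantile(pooled, percentile / 100, type = 7))
}

#' Detect fluorescence transient onsets
#'
#' For each upward crossing of the derivative threshold, the event onset is
#' the nearest preceding derivative zero-crossing (the time point where the
#' rise began). Consecutive threshold crossings with no intervening
#' zero-crossing are compressed into one event at the first time point.
#' Onsets within \code{edge_exclusion} seconds of either end of the trace
#' are dropped.
#'
#' @param trace a \code{RatioTrace} data.frame (columns \code{t},
#'   \code{percent_dRR}).
#' @param threshold derivative threshold from [poolDerivativeThreshold()].
#' @param config an [eventConfig()].
#' @return An [EventSeries-class].
#' @export
detectEvents <- function(trace, threshold, config = eventConfig()) {
  stopifnot(inherits(config, "EventConfig"))
  t <- trace$t; x <- trace$percent_dRR
  n <- length(t)
  if (n < 3) stop("trace too short")
  d <- diff(x) / diff(t)
  # an event is a transient *increase*: the derivative must be positive at
  # the crossing even if the pooled threshold is non-positive
  up <- d >= threshold & d > 0
  crossings <- which(up[-1] & !up[-length(up)]) + 1L
  if (up[1]) crossings <- c(1L, crossings)
  onsetsIdx <- integer(0)
  for (k in crossings) {
    j <- k
    while (j > 1 && d[j] > 0) j <- j - 1
    # j is now the last non-positive derivative sample before the rise
    if (d[j] > 0) next   # rise starts before the trace: onset unknown
    onsetsIdx <- c(onsetsIdx, j)
  }
  onsetsIdx <- unique(onsetsIdx)
  onsets <- t[onsetsIdx]
  keep <- onsets >= t[1] + config$edge_exclusion &
          onsets <= t[n] - config$edge_exclusion
  EventSeries(sort(onsets[keep]), tRange = range(t))
}

# Greedy nearest-available pairing of two sorted onset vectors within a
# time window; returns a 2-column index matrix of pairs.
greedyPairs <- function(a, b, window) {
  usedB <- rep(FALSE, length(b))
  pairs <- NULL
  for (i in seq_along(a)) {
    cand <- which(!usedB & abs(b - a[i]) <= window)
    if (!length(cand)) next
    j <- cand[which.min(abs(b[cand] - a[i]))]
    usedB[j] <- TRUE
    pairs <- rbind(pairs, c(i, j))
  }
  pairs
}

#' Reconcile bilateral event series
#'
#' For strongly covarying pairs (MDN, dMAN): events detected on both sides
#' within \code{pair_merge_window} of one another are retained on both
#' sides; an event detected on one side only is also added to the partner's
#' event library (flagged \code{copied_from_partner}), unless the copy would
#' fall inside the partner's edge-exclusion zone. For independent pairs
#' (A1): events detected on both sides within
#' \code{independent_veto_window} are discarded from both sides.
#'
#' @param left,right [EventSeries-class] objects on the same timebase.
#' @param config an [eventConfig()]; \code{covarying_pair} selects the rule.
#' @return list with reconciled \code{left} and \code{right}
#'   [EventSeries-class] objects.
#' @export
reconcileBilateral <- function(left, right, config = eventConfig()) {
  stopifnot(is(left, "EventSeries"), is(right, "EventSeries"),
            inherits(config, "EventConfig"))
  lOn <- left@onsets; rOn <- right@onsets
  tr <- left@tRange
  if (config$covarying_pair) {
    pairs <- greedyPairs(lOn, rOn, config$pair_merge_window)
    lPaired <- if (is.null(pairs)) integer(0) else pairs[, 1]
    rPaired <- if (is.null(pairs)) integer(0) else pairs[, 2]
    inEdge <- function(x) x < tr[1] + config$edge_exclusion |
                          x > tr[2] - config$edge_exclusion
    copyToR <- setdiff(seq_along(lOn), lPaired)
    copyToR <- copyToR[!inEdge(lOn[copyToR])]
    copyToL <- setdiff(seq_along(rOn), rPaired)
    copyToL <- copyToL[!inEdge(rOn[copyToL])]
    mergeSide <- function(own, ownSrc, copied) {
      on <- c(own, copied)
      src <- c(ownSrc, rep("copied_from_partner", length(copied)))
      o <- order(on)
      dup <- duplicated(on[o])
      EventSeries(on[o][!dup], tRange = tr, source = src[o][!dup])
    }
    list(left = mergeSide(lOn, left@source, rOn[copyToL]),
         right = mergeSide(rOn, right@source, lOn[copyToR]))
  } else {
    pairs <- greedyPairs(lOn, rOn, config$independent_veto_window)
    lDrop <- if (is.null(pairs)) integer(0) else pairs[, 1]
    rDrop <- if (is.null(pairs)) integer(0) else pairs[, 2]
    list(left = EventSeries(lOn[setdiff(seq_along(lOn), lDrop)], tRange = tr,
                            vetoed = lOn[lDrop]),
         right = EventSeries(rOn[setdiff(seq_along(rOn), rDrop)], tRange = tr,
                             vetoed = rOn[rDrop]))
  }
}

#' Event-triggered summary of neural and behavioral signals
#'
#' Windows every signal to +/- \code{summary_window} seconds around each
#' event onset (onset at 0 s), resamples to \code{summary_rate}, and
#' computes the pointwise mean with a percentile-bootstrap 95% CI over
#' events (resampling events with replacement). %dR/R windows are
#' baseline-subtracted so the value at 0 s is exactly zero.
#'
#' @param events an [EventSeries-class].
#' @param traces named list of data.frames with a \code{t} column; a column
#'   named \code{percent_dRR} is baseline-subtracted at the event time.
#' @param config an [eventConfig()].
#' @param seed RNG seed for the bootstrap.
#' @return list of class \code{"EventTriggeredSummary"}: \code{t_rel},
#'   \code{signals} (per signal column: \code{mean}, \code{ci_lo},
#'   \code{ci_hi}), \code{n_events}.
#' @export
eventTriggeredSummary <- function(events, traces, config = eventConfig(),
                                  seed = 1) {
  stopifnot(is(events, "EventSeries"), inherits(config, "EventConfig"))
  W <- config$summary_window
  tRel <- seq(-W, W, by = 1 / config$summary_rate)
  zeroIdx <- which.min(abs(tRel))
  lo <- max(vapply(traces, function(s) min(s$t), numeric(1)))
  hi <- min(vapply(traces, function(s) max(s$t), numeric(1)))
  onsets <- events@onsets
  onsets <- onsets[onsets - W >= lo & onsets + W <= hi]
  if (!length(onsets))
    stop("no event with a full +/-", W, " s window of data")
  nE <- length(onsets)
  signals <- list()
  set.seed(seed)
  for (nm in names(traces)) {
    tr <- traces[[nm]]
    for (col in setdiff(names(tr), "t")) {
      M <- vapply(onsets, function(on) interp1(tr$t, tr[[col]], on + tRel),
                  numeric(length(tRel)))
      M <- matrix(M, nrow = length(tRel))
      if (col == "percent_dRR")
        M <- sweep(M, 2, M[zeroIdx, ])
      mu <- rowMeans(M)
      if (nE == 1) {
        ci <- cbind(mu, mu)
      } else {
        boot <- matrix(0, length(tRel), config$n_bootstrap)
        for (b in seq_len(config$n_bootstrap))
          boot[, b] <- rowMeans(M[, sample.int(nE, nE, replace = TRUE),
                                  drop = FALSE])
        ci <- t(apply(boot, 1, stats::quantile, probs = c(0.025, 0.975)))
      }
      signals[[col]] <- list(mean = mu, ci_lo = pmin(ci[, 1], mu),
                             ci_hi = pmax(ci[, 2], mu))
    }
  }
  structure(list(t_rel = tRel, signals = signals, n_events = nE),
            class = "EventTriggeredSummary")
}

#' Time-shuffled control summary
#'
#' Replaces the detected events with uniformly random time points (drawn
#' away from the trace edges) and computes the identical event-triggered
#' summary; event-locked structure in the real summary should be absent
#' here.
#'
#' @param traces as in [eventTriggeredSummary()].
#' @param n_events number of random time points to draw.
#' @param config an [eventConfig()].
#' @param seed RNG seed (drives both the draw and the bootstrap).
#' @return an \code{EventTriggeredSummary}.
#' @export
shuffledControl <- function(traces, n_events, config = eventConfig(),
                            seed = 1) {
  if (n_events < 1) stop("n_events must be >= 1")
  lo <- max(vapply(traces, function(s) min(s$t), numeric(1)))
  hi <- min(vapply(traces, function(s) max(s$t), numeric(1)))
  m <- max(config$edge_exclusion, config$summary_window)
  if (hi - m <= lo + m) stop("trace too short for shuffled windows")
  set.seed(seed)
  onsets <- sort(stats::runif(n_events, lo + m, hi - m))
  onsets <- onsets + seq(0, 1e-9, length.out = n_events)  # strict ordering
  ev <- EventSeries(onsets, tRange = c(lo, hi))
  eventTriggeredSummary(ev, traces, config, seed = seed + 1)
}

#' Rank events by behavioral exemplar criteria
#'
#' Ranks detected events by the treadmill statistic characterizing each
#' behavior: \code{push_down} by the difference between the mean forward
#' velocity up to 2 s after and 1 s before the event (descending);
#' \code{backward} by the mean forward velocity up to 2 s after (ascending:
#' deepest backward walking first); \code{yaw_left} / \code{yaw_right} by
#' the mean rotational velocity up to 2 s after (descending / ascending).
#'
#' @param events an [EventSeries-class].
#' @param velocity data.frame from [convertOpticFlow()].
#' @param criterion one of \code{"push_down"}, \code{"backward"},
#'   \code{"yaw_left"}, \code{"yaw_right"}.
#' @return data.frame \code{(onset, stat)} ordered best-first.
#' @export
selectExemplarEvents <- function(events, velocity,
                                 criterion = c("push_down", "backward",
                                               "yaw_left", "yaw_right")) {
  criterion <- match.arg(criterion)
  stopifnot(is(events, "EventSeries"))
  onsets <- events@onsets
  if (!length(onsets)) stop("no events to rank")
  tmin <- min(velocity$t); tmax <- max(velocity$t)
  winMean <- function(col, on, a, b) {
    tt <- velocity$t
    idx <- tt >= on + a & tt <= on + b
    mean(velocity[[col]][idx])
  }
  ok <- onsets - 1 >= tmin & onsets + 2 <= tmax
  if (any(!ok)) warning(sum(!ok), " event(s) skipped: window exceeds trace")
  onsets <- onsets[ok]
  stat <- vapply(onsets, function(on) switch(criterion,
    push_down = winMean("v_forward", on, 0, 2) - winMean("v_forward", on, -1, 0),
    backward = winMean("v_forward", on, 0, 2),
    yaw_left = winMean("v_rotation", on, 0, 2),
    yaw_right = winMean("v_rotation", on, 0, 2)), numeric(1))
  o <- switch(criterion,
    push_down = order(-stat),
    backward = order(stat),
    yaw_left = order(-stat),
    yaw_right = order(stat))
  data.frame(onset = onsets[o], stat = stat[o])
}
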
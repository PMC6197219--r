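#' @import methods
NULL

#' TwoChannelMovie: co-registered activity + structural image stacks
#'
#' Container for a two-channel 2-photon recording: an activity channel
#' (GCaMP6s) and a structural channel (tdTomato, an activity-independent
#' fluorophore used as an anatomical fiduciary). Both channels are stored as
#' \code{[row, col, frame]} arrays sharing one frame clock.
#'
#' @slot activity numeric array \code{[h, w, T]}, activity-reporter channel.
#' @slot structural numeric array \code{[h, w, T]}, structural channel.
#' @slot frameRate scalar, frames per second.
#'
#' @seealso [activityChannel()], [structuralChannel()], [frameTimes()]
#' @export
setClass("TwoChannelMovie",
  representation(activity = "array", structural = "array",
                 frameRate = "numeric"))

setValidity("TwoChannelMovie", function(object) {
  a <- object@activity; s <- object@structural
  if (length(dim(a)) != 3 || length(dim(s)) != 3)
    return("channels must be [row, col, frame] arrays")
  if (!identical(dim(a), dim(s)))
    return("activity and structural channels must have identical dimensions")
  if (length(object@frameRate) != 1 || !is.finite(object@frameRate) ||
      object@frameRate <= 0)
    return("frameRate must be a positive scalar")
  if (anyNA(a) || anyNA(s)) return("channels must not contain NA")
  TRUE
})

#' Construct a TwoChannelMovie
#'
#' @param activity,structural numeric arrays \code{[h, w, T]}.
#' @param frameRate frames per second.
#' @return A [TwoChannelMovie-class] object.
#' @examples
#' m <- TwoChannelMovie(array(1, c(4, 4, 3)), array(1, c(4, 4, 3)), 8)
#' nFrames(m)
#' @export
TwoChannelMovie <- function(activity, structural, frameRate) {
  new("TwoChannelMovie", activity = activity, structural = structural,
      frameRate = as.numeric(frameRate))
}

#' @describeIn TwoChannelMovie-class activity-channel array.
#' @param object,x a \code{TwoChannelMovie}.
#' @export
setGeneric("activityChannel", function(object) standardGeneric("activityChannel"))

#' @rdname TwoChannelMovie-class
#' @export
setMethod("activityChannel", "TwoChannelMovie", function(object) object@activity)

#' @rdname TwoChannelMovie-class
#' @export
setGeneric("structuralChannel",
           function(object) standardGeneric("structuralChannel"))

#' @rdname TwoChannelMovie-class
#' @export
setMethod("structuralChannel", "TwoChannelMovie",
          function(object) object@structural)

#' @rdname TwoChannelMovie-class
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname TwoChannelMovie-class
#' @export
setMethod("frameRate", "TwoChannelMovie", function(object) object@frameRate)

#' @rdname TwoChannelMovie-class
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname TwoChannelMovie-class
#' @export
setMethod("nFrames", "TwoChannelMovie", function(object) dim(object@activity)[3])

#' @rdname TwoChannelMovie-class
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @describeIn TwoChannelMovie-class frame timestamps in seconds (frame 1 at 0).
#' @export
setMethod("frameTimes", "TwoChannelMovie", function(object)
  (seq_len(nFrames(object)) - 1) / object@frameRate)

setMethod("show", "TwoChannelMovie", function(object) {
  d <- dim(object@activity)
  cat(sprintf(
    "TwoChannelMovie: %d x %d pixels, %d frames at %.3g Hz (%.1f s)\n",
    d[1], d[2], d[3], object@frameRate, d[3] / object@frameRate))
  cat(sprintf("  activity   range [%.3g, %.3g]\n", min(object@activity),
              max(object@activity)))
  cat(sprintf("  structural range [%.3g, %.3g]\n", min(object@structural),
              max(object@structural)))
})

#' EventSeries: detected fluorescence transient onsets
#'
#' Onset timestamps of detected fluorescence transients for one neuron,
#' with per-event provenance: \code{"detected"} for onsets found by the
#' derivative-threshold detector, \code{"copied_from_partner"} for onsets
#' inherited from the contralateral neuron under the covarying-pair rule.
#' Onsets discarded by the independent-pair veto are kept in \code{vetoed}.
#'
#' @slot onsets numeric, strictly increasing onset times in seconds.
#' @slot source character, one provenance flag per onset.
#' @slot vetoed numeric, onsets removed by bilateral reconciliation.
#' @slot tRange numeric(2), time support of the source trace in seconds.
#' @export
setClass("EventSeries",
  representation(onsets = "numeric", source = "character",
                 vetoed = "numeric", tRange = "numeric"))

setValidity("EventSeries", function(object) {
  if (length(object@source) != length(object@onsets))
    return("one source flag per onset is required")
  if (is.unsorted(object@onsets, strictly = TRUE))
    return("onsets must be strictly increasing")
  if (!all(object@source %in% c("detected", "copied_from_partner")))
    return("unknown source flag")
  if (length(object@tRange) != 2 || object@tRange[1] >= object@tRange[2])
    return("tRange must be (start, end) with start < end")
  TRUE
})

#' Construct an EventSeries
#'
#' @param onsets numeric onset times (s), strictly increasing.
#' @param tRange numeric(2): time support of the source trace.
#' @param source provenance flags (recycled if length 1).
#' @param vetoed onsets discarded during reconciliation.
#' @return An [EventSeries-class] object.
#' @export
EventSeries <- function(onsets = numeric(0), tRange,
                        source = rep("detected", length(onsets)),
                        vetoed = numeric(0)) {
  if (length(source) == 1 && length(onsets) > 1)
    source <- rep(source, length(onsets))
  new("EventSeries", onsets = as.numeric(onsets), source = as.character(source),
      vetoed = as.numeric(vetoed), tRange = as.numeric(tRange))
}

#' @rdname EventSeries-class
#' @param object an \code{EventSeries}.
#' @export
setGeneric("eventOnsets", function(object) standardGeneric("eventOnsets"))

#' @rdname EventSeries-class
#' @export
setMethod("eventOnsets", "EventSeries", function(object) object@onsets)

#' @rdname EventSeries-class
#' @export
setGeneric("eventSource", function(object) standardGeneric("eventSource"))

#' @rdname EventSeries-class
#' @export
setMethod("eventSource", "EventSeries", function(object) object@source)

#' @rdname EventSeries-class
#' @export
setGeneric("nEvents", function(object) standardGeneric("nEvents"))

#' @rdname EventSeries-class
#' @export
setMethod("nEvents", "EventSeries", function(object) length(object@onsets))

setMethod("show", "EventSeries", function(object) {
  cat(sprintf("EventSeries: %d events on [%.1f, %.1f] s (%d copied, %d vetoed)\n",
              length(object@onsets), object@tRange[1], object@tRange[2],
              sum(object@source == "copied_from_partner"),
              length(object@vetoed)))
})
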
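# Footprint time-course pipeline: ROI mean extraction, background
# subtraction, baseline normalization, treatment-window summaries.

#' Construct a TIRF image stack
#'
#' @param frames numeric array `(rows, cols, frames)` in camera units.
#' @param channel channel label, e.g. `"biosensor"`.
#' @param frameInterval seconds between frames.
#' @param startTime acquisition time of the first frame (s).
#' @return A [TirfStack-class].
#' @export
tirfStack <- function(frames, channel = "biosensor", frameInterval = 10,
                      startTime = 0) {
  new("TirfStack",
    frames = frames, channelLabel = as.character(channel),
    frameInterval = as.numeric(frameInterval),
    startTime = as.numeric(startTime)
  )
}

#' @rdname tirfStack
#' @param object a [TirfStack-class].
#' @export
setMethod("frames", "TirfStack", function(object) object@frames)

#' @rdname tirfStack
#' @export
setMethod("channelLabel", "TirfStack", function(object)
  object@channelLabel)

#' @rdname tirfStack
#' @export
setMethod("frameInterval", "TirfStack", function(object)
  object@frameInterval)

#' @rdname tirfStack
#' @export
setMethod("frameTimes", "TirfStack", function(object) {
  object@startTime +
    (seq_len(dim(object@frames)[3L]) - 1L) * object@frameInterval
})

#' Construct an ROI set
#'
#' @param cellMask logical matrix marking the cell footprint.
#' @param backgroundMask logical matrix marking the background region;
#'   same dimensions, disjoint from the footprint.
#' @return A [RoiSet-class].
#' @export
roiSet <- function(cellMask, backgroundMask) {
  new("RoiSet", cellMask = cellMask, backgroundMask = backgroundMask)
}

#' @rdname roiSet
#' @param object a [RoiSet-class].
#' @export
setMethod("cellMask", "RoiSet", function(object) object@cellMask)

#' @rdname roiSet
#' @export
setMethod("backgroundMask", "RoiSet", function(object)
  object@backgroundMask)

#' Extract the per-frame ROI mean intensity
#'
#' Arithmetic mean of the pixels under `mask`, one value per frame.
#'
#' @param stack a [TirfStack-class].
#' @param mask logical matrix with the dimensions of one frame.
#' @return Numeric vector, one mean per frame (camera units).
#' @export
extractTrace <- function(stack, mask) {
  stopifnot(is(stack, "TirfStack"), is.logical(mask))
  d <- dim(stack@frames)
  if (!identical(dim(mask), d[1:2]))
    stop("mask dimensions must match the frame dimensions")
  if (!any(mask))
    stop("empty mask")
  idx <- which(mask)
  vapply(seq_len(d[3L]),
         function(t) mean(stack@frames[, , t][idx]),
         numeric(1))
}

#' Subtract the background ROI trace
#'
#' Elementwise `cell - background`. Non-positive corrected values are
#' kept (clipping would bias the subsequent normalization) but flagged
#' with a warning, since a non-positive baseline makes normalization
#' fail.
#'
#' @param cell,background numeric vectors of equal length (camera units).
#' @return Numeric vector of corrected intensities.
#' @export
backgroundSubtract <- function(cell, background) {
  stopifnot(is.numeric(cell), is.numeric(background))
  if (length(cell) != length(background))
    stop("cell and background traces must have equal length")
  corrected <- cell - background
  if (any(corrected <= 0))
    warning("corrected trace contains non-positive values; ",
            "baseline normalization may fail")
  corrected
}

#' Normalize a trace to its pre-treatment baseline
#'
#' Divides the trace by the mean of the samples falling in the baseline
#' window `[-baselineDuration, 0)` seconds relative to treatment
#' application, so the baseline mean of the output is 1. The default
#' 60 s window is a convention, not a constant: pass 120 for a
#' two-minute baseline.
#'
#' @param trace numeric vector (typically background-corrected).
#' @param time numeric vector of sample times, seconds relative to
#'   application (t = 0).
#' @param baselineDuration length of the pre-application window (s).
#' @return Normalized numeric vector (dimensionless).
#' @export
normalizeBaseline <- function(trace, time, baselineDuration = 60) {
  stopifnot(is.numeric(trace), is.numeric(time),
            length(trace) == length(time))
  inBaseline <- time >= -baselineDuration & time < 0
  if (!any(inBaseline))
    stop("no samples in the baseline window [-", baselineDuration, ", 0)")
  b <- mean(trace[inBaseline])
  if (b <= 0)
    stop("non-positive baseline mean; cannot normalize")
  trace / b
}

#' Run the full footprint pipeline on one stack
#'
#' Extracts the footprint and background ROI means, subtracts the
#' background, re-expresses time relative to treatment application and
#' normalizes to the pre-application baseline.
#'
#' @param stack a [TirfStack-class].
#' @param rois a [RoiSet-class].
#' @param applicationTime treatment application time, on the same clock
#'   as `frameTimes(stack)` (s).
#' @param baselineDuration baseline window length (s); see
#'   [normalizeBaseline()].
#' @return A [FootprintTrace-class].
#' @export
footprintTrace <- function(stack, rois, applicationTime,
                           baselineDuration = 60) {
  stopifnot(is(rois, "RoiSet"))
  raw <- extractTrace(stack, rois@cellMask)
  bg <- extractTrace(stack, rois@backgroundMask)
  corrected <- backgroundSubtract(raw, bg)
  time <- frameTimes(stack) - applicationTime
  new("FootprintTrace",
    time = time, raw = raw, background = bg, corrected = corrected,
    normalized = normalizeBaseline(corrected, time, baselineDuration)
  )
}

#' Define a treatment summary window
#'
#' @param start,end window bounds in minutes relative to application;
#'   the window is half-open, `[start, end)`.
#' @return A [TreatmentWindow-class].
#' @export
treatmentWindow <- function(start, end) {
  new("TreatmentWindow", start = as.numeric(start), end = as.numeric(end))
}

#' Named window presets
#'
#' Commonly used summary windows for the two channels: the biosensor
#' response is summarized earlier (it peaks and partially relaxes) and
#' the channel-trafficking response later (it rises without reversal).
#' Two variants of each are provided because reasonable analyses differ
#' on the exact placement:
#' `biosensor_early` = 4–6 min, `biosensor_late` = 6–8 min,
#' `channel_early` = 8–10 min, `channel_late` = 10–12 min.
#'
#' @return Named list of [TreatmentWindow-class] objects.
#' @export
windowPresets <- function() {
  list(
    biosensor_early = treatmentWindow(4, 6),
    biosensor_late = treatmentWindow(6, 8),
    channel_early = treatmentWindow(8, 10),
    channel_late = treatmentWindow(10, 12)
  )
}

.resolveWindow <- function(window) {
  if (is(window, "TreatmentWindow")) return(window)
  if (is.character(window) && length(window) == 1L) {
    presets <- windowPresets()
    if (!window %in% names(presets))
      stop("unknown window preset '", window, "'; available: ",
           paste(names(presets), collapse = ", "))
    return(presets[[window]])
  }
  stop("window must be a TreatmentWindow or a preset name")
}

#' Average a normalized trace over a treatment window
#'
#' Mean of the normalized samples whose timestamps fall in
#' `[start, end)` minutes relative to application (half-open, so frame
#' timestamps on a boundary are counted deterministically).
#'
#' @param x a [FootprintTrace-class], or a numeric vector of normalized
#'   values (then supply `time` in seconds).
#' @param window a [TreatmentWindow-class] or a preset name from
#'   [windowPresets()].
#' @param time sample times in seconds (numeric method only).
#' @param ... unused.
#' @return The window mean (dimensionless).
#' @export
setMethod("windowSummary", "FootprintTrace",
  function(x, window, ...) {
    windowSummary(x@normalized, window, time = x@time)
  })

#' @rdname windowSummary-FootprintTrace-method
#' @export
setMethod("windowSummary", "numeric",
  function(x, window, time, ...) {
    window <- .resolveWindow(window)
    stopifnot(is.numeric(time), length(time) == length(x))
    inWin <- time >= window@start * 60 & time < window@end * 60
    if (!any(inWin))
      stop("no samples in the window [", window@start, ", ",
           window@end, ") min")
    mean(x[inWin])
  })

setMethod("show", "TirfStack", function(object) {
  d <- dim(object@frames)
  cat("TirfStack '", object@channelLabel, "': ",
      d[1L], " x ", d[2L], " px, ", d[3L], " frames @ ",
      object@frameInterval, " s\n", sep = "")
})

setMethod("show", "FootprintTrace", function(object) {
  cat("FootprintTrace: ", length(object@time), " frames, t = [",
      min(object@time), ", ", max(object@time), "] s\n",
      "  normalized range: [",
      sprintf("%.3f", min(object@normalized)), ", ",
      sprintf("%.3f", max(object@normalized)), "]\n", sep = "")
})

setMethod("show", "TreatmentWindow", function(object) {
  cat("TreatmentWindow [", object@start, ", ", object@end, ") min\n",
      sep = "")
})

#' Tidy export of a footprint trace
#'
#' @param x a [FootprintTrace-class].
#' @param row.names,optional,... passed over from the generic; unused.
#' @return `data.frame` with columns time_s, raw, background, corrected,
#'   normalized.
#' @exportS3Method base::as.data.frame
as.data.frame.FootprintTrace <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  data.frame(
    time_s = x@time, raw = x@raw, background = x@background,
    corrected = x@corrected, normalized = x@normalized
  )
}
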
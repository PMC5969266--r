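# Accessors and show methods for the core classes.

#' @describeIn EogRecording-accessors vertical EOG channel (microvolts)
#' @export
veog <- function(x) {
  stopifnot(is(x, "EogRecording"))
  x@veog
}

#' Accessors for EogRecording objects
#'
#' @param x an [EogRecording-class] object.
#' @return the corresponding slot value.
#' @name EogRecording-accessors
NULL

#' @describeIn EogRecording-accessors horizontal EOG channel (microvolts)
#' @export
heog <- function(x) {
  stopifnot(is(x, "EogRecording"))
  x@heog
}

#' @describeIn EogRecording-accessors sample times in seconds
#' @export
eogTime <- function(x) {
  stopifnot(is(x, "EogRecording"))
  x@time
}

#' @describeIn EogRecording-accessors sampling rate in Hz
#' @export
samplingRate <- function(x) {
  stopifnot(is(x, "EogRecording"))
  x@rate
}

#' @describeIn EogRecording-accessors recording duration in seconds
#' @export
eogDuration <- function(x) {
  stopifnot(is(x, "EogRecording"))
  length(x@time) / x@rate
}

#' @describeIn EogRecording-accessors generator ground truth (list; empty for
#'   real recordings)
#' @export
eogTruth <- function(x) {
  stopifnot(is(x, "EogRecording"))
  x@truth
}

#' Accessors for time-activity curves
#'
#' @param x a [TimeActivityCurve-class].
#' @return numeric vector (times in minutes or activity values).
#' @name TimeActivityCurve-accessors
NULL

#' @describeIn TimeActivityCurve-accessors frame start times (min)
#' @export
frameStart <- function(x) {
  stopifnot(is(x, "TimeActivityCurve"))
  x@frameStart
}

#' @describeIn TimeActivityCurve-accessors frame end times (min)
#' @export
frameEnd <- function(x) {
  stopifnot(is(x, "TimeActivityCurve"))
  x@frameEnd
}

#' @describeIn TimeActivityCurve-accessors frame mid-times (min)
#' @export
frameMid <- function(x) {
  stopifnot(is(x, "TimeActivityCurve"))
  (x@frameStart + x@frameEnd) / 2
}

#' @describeIn TimeActivityCurve-accessors framewise activity
#' @export
activity <- function(x) {
  stopifnot(is(x, "TimeActivityCurve"))
  x@activity
}

#' Accessors for Patlak fits and Ki volumes
#'
#' `ki()` returns the influx constant: the fitted slope for a
#' [PatlakFit-class], or the 3-D value grid for a [KiVolume-class].
#'
#' @param x a [PatlakFit-class] or [KiVolume-class].
#' @name ki
#' @export
ki <- function(x) {
  if (is(x, "PatlakFit")) return(x@ki)
  if (is(x, "KiVolume")) return(x@values)
  stop("ki() expects a PatlakFit or KiVolume")
}

#' @describeIn ki fitted Patlak intercept (distribution-volume scale)
#' @export
patlakIntercept <- function(x) {
  stopifnot(is(x, "PatlakFit"))
  x@intercept
}

#' @describeIn ki coefficient of determination of the Patlak line fit
#' @export
patlakRsq <- function(x) {
  stopifnot(is(x, "PatlakFit"))
  x@rSquared
}

#' @describeIn ki logical 3-D grid of a region mask
#' @export
roiMask <- function(x) {
  stopifnot(is(x, "RoiMask"))
  x@mask
}

#' @describeIn ki 4x4 grid-to-world affine of a KiVolume or RoiMask
#' @export
gridAffine <- function(x) {
  stopifnot(is(x, "KiVolume") || is(x, "RoiMask"))
  x@affine
}

setMethod("show", "EogRecording", function(object) {
  cat(sprintf("EogRecording: %.1f s at %g Hz (%d samples)\n",
              eogDuration(object), object@rate, length(object@time)))
  if (length(object@truth))
    cat(sprintf("  synthetic truth: %d planted blinks\n",
                length(object@truth$blinkOnsets)))
})

setMethod("show", "TimeActivityCurve", function(object) {
  cat(sprintf("TimeActivityCurve: %d frames, %.1f-%.1f min, peak %.3g\n",
              length(object@activity), min(object@frameStart),
              max(object@frameEnd), max(object@activity)))
})

setMethod("show", "PatlakFit", function(object) {
  cat(sprintf(
    "PatlakFit: Ki = %.6g /min, intercept = %.4g (R2 = %.4f, %d frames in %g-%g min)\n",
    object@ki, object@intercept, object@rSquared, object@nPoints,
    object@window[1], object@window[2]))
})

setMethod("show", "KiVolume", function(object) {
  d <- dim(object@values)
  nbad <- sum(!is.finite(object@values))
  cat(sprintf("KiVolume: %d x %d x %d voxels (%g x %g x %g mm), %d non-fittable\n",
              d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
              object@voxelSize[3], nbad))
})

setMethod("show", "RoiMask", function(object) {
  d <- dim(object@mask)
  cat(sprintf("RoiMask: %d / %d voxels in %d x %d x %d grid\n",
              sum(object@mask), length(object@mask), d[1], d[2], d[3]))
})
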
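#' @import methods
NULL

#' Two-channel electro-oculography recording
#'
#' Container for a bipolar EOG recording on a uniform time grid: a vertical
#' channel (vEOG, capturing blinks) and a horizontal channel (hEOG, capturing
#' saccades), both in microvolts. Recordings produced by [simulateEog()]
#' additionally carry their ground truth (planted blink onsets, artifact
#' intervals) in the `truth` slot.
#'
#' @slot time numeric, sample times in seconds (uniform grid starting at 0).
#' @slot veog numeric, vertical EOG in microvolts.
#' @slot heog numeric, horizontal EOG in microvolts.
#' @slot rate numeric(1), sampling rate in Hz.
#' @slot truth list, generator ground truth (empty for real data).
#'
#' @seealso [simulateEog()], [preprocessVeog()], [detectBlinks()]
#' @export
setClass("EogRecording",
  slots = c(time = "numeric", veog = "numeric", heog = "numeric",
            rate = "numeric", truth = "list"),
  prototype = prototype(truth = list())
)

setValidity("EogRecording", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@veog) != n || length(object@heog) != n)
    msg <- c(msg, "time, veog and heog must have equal length")
  if (length(object@rate) != 1 || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (n > 1) {
    dt <- diff(object@time)
    if (any(abs(dt - 1 / object@rate) > 1e-6 / object@rate))
      msg <- c(msg, "time must be a uniform grid at the stated rate")
  }
  if (length(msg)) msg else TRUE
})

#' Time-activity curve for a dynamic PET frame sequence
#'
#' Framewise tracer activity for a region or voxel: frame start/end times in
#' minutes and one (non-negative, finite) activity value per frame.
#'
#' @slot frameStart numeric, frame start times (minutes).
#' @slot frameEnd numeric, frame end times (minutes).
#' @slot activity numeric, mean activity per frame (arbitrary units).
#'
#' @seealso [simulateReferenceTac()], [simulateTissueTac()], [patlakTransform()]
#' @export
setClass("TimeActivityCurve",
  slots = c(frameStart = "numeric", frameEnd = "numeric", activity = "numeric")
)

setValidity("TimeActivityCurve", function(object) {
  msg <- character()
  ns <- length(object@frameStart)
  if (ns == 0) msg <- c(msg, "at least one frame is required")
  if (length(object@frameEnd) != ns || length(object@activity) != ns)
    msg <- c(msg, "frameStart, frameEnd and activity must have equal length")
  else {
    if (any(object@frameEnd <= object@frameStart))
      msg <- c(msg, "every frame must have positive duration")
    if (ns > 1 && any(object@frameStart[-1] < object@frameEnd[-ns] - 1e-9))
      msg <- c(msg, "frames must be ordered and non-overlapping")
    if (any(!is.finite(object@activity)) || any(object@activity < 0))
      msg <- c(msg, "activity must be finite and non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Patlak graphical-analysis fit
#'
#' Result of the windowed ordinary-least-squares line fit to Patlak-transformed
#' points: the slope is the net influx constant Ki (per minute); the intercept
#' is scaled to the tracer distribution volume of the reference region.
#'
#' @slot ki numeric(1), fitted influx constant (1/min).
#' @slot intercept numeric(1), fitted intercept (unitless).
#' @slot rSquared numeric(1), coefficient of determination of the line fit.
#' @slot nPoints integer(1), number of frames inside the fit window.
#' @slot window numeric(2), fit window (start, end) in minutes.
#'
#' @seealso [fitPatlak()]
#' @export
setClass("PatlakFit",
  slots = c(ki = "numeric", intercept = "numeric", rSquared = "numeric",
            nPoints = "integer", window = "numeric")
)

setValidity("PatlakFit", function(object) {
  msg <- character()
  if (object@nPoints < 2L) msg <- c(msg, "a fit needs at least 2 points")
  if (length(object@window) != 2 || diff(object@window) <= 0)
    msg <- c(msg, "window must be an increasing (start, end) pair")
  if (length(msg)) msg else TRUE
})

#' Voxel grid of influx constants (Ki map)
#'
#' A 3-D grid of per-minute Ki values together with its voxel size and
#' grid-to-world affine. Voxel indices are 0-based in world-coordinate
#' computations.
#'
#' @slot values 3-D numeric array of Ki values (NaN marks non-fittable voxels).
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot affine 4x4 grid-to-world transform.
#'
#' @seealso [kiImage()], [makeTemplateMask()], [extractRoi()]
#' @export
setClass("KiVolume",
  slots = c(values = "array", voxelSize = "numeric", affine = "matrix")
)

setValidity("KiVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3)
    msg <- c(msg, "values must be a 3-D array")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive lengths")
  if (!all(dim(object@affine) == c(4, 4)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})

#' Boolean region-of-interest mask on a Ki grid
#'
#' @slot mask 3-D logical array, TRUE inside the region.
#' @slot affine 4x4 grid-to-world transform of the parent grid.
#'
#' @seealso [makeTemplateMask()], [extractRoi()], [voxelwiseRegression()]
#' @export
setClass("RoiMask", slots = c(mask = "array", affine = "matrix"))

setValidity("RoiMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3 || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3-D logical array")
  if (!all(dim(object@affine) == c(4, 4)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  if (length(msg)) msg else TRUE
})
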
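# Synthetic dynamic-PET generator: reference and tissue time-activity curves
# satisfying the irreversible-uptake Patlak relation with known Ki, and 4-D
# dynamic volumes built voxel-wise from a Ki truth map.

#' Default dynamic frame table for an 89-minute scan
#'
#' Frame timing emulating a dynamic [18F]DOPA acquisition: short frames early
#' (to sample the fast kinetics after injection) and 5-min frames late, 24
#' frames covering 0-89 min.
#'
#' @return data.frame with columns `frame_start_min`, `frame_end_min`.
#' @export
defaultFrameTable <- function() {
  dur <- c(rep(1, 4), rep(2, 3), rep(3, 3), rep(5, 14))
  end <- cumsum(dur)
  data.frame(frame_start_min = c(0, end[-length(end)]), frame_end_min = end)
}

#' Simulate a reference-region (cerebellar) time-activity curve
#'
#' A gamma-variate input shape `A (t / tp)^alpha exp(alpha (1 - t / tp))`,
#' zero at injection, rising to its peak at `peakTime` and decaying after --
#' the smooth rise-then-decay shape expected of a region without irreversible
#' uptake. Deterministic given its parameters.
#'
#' @param frames frame-timing data.frame (`frame_start_min`, `frame_end_min`).
#' @param peakTime minutes to peak activity (default 10, well before the
#'   24-min start of the Patlak linear window).
#' @param shape gamma-variate shape parameter alpha.
#' @param peakActivity activity at the peak (arbitrary units).
#' @return a [TimeActivityCurve-class] evaluated at frame mid-times.
#' @export
#' @examples
#' ref <- simulateReferenceTac()
simulateReferenceTac <- function(frames = defaultFrameTable(), peakTime = 10,
                                 shape = 2, peakActivity = 100) {
  if (is.null(frames) || nrow(frames) == 0) stop("frame table is empty")
  if (any(frames$frame_end_min <= frames$frame_start_min))
    stop("frames must have positive duration")
  stopifnot(peakTime > 0, shape > 0, peakActivity > 0)
  mid <- (frames$frame_start_min + frames$frame_end_min) / 2
  a <- peakActivity * (mid / peakTime)^shape * exp(shape * (1 - mid / peakTime))
  a[mid <= 0] <- 0
  new("TimeActivityCurve", frameStart = frames$frame_start_min,
      frameEnd = frames$frame_end_min, activity = a)
}

#' Simulate a tissue time-activity curve with known influx constant
#'
#' Constructs `tissue(t) = kiTrue * CumInt(ref)(t) + vRef * ref(t)` at frame
#' mid-times, where `CumInt` is the same anchored trapezoidal
#' cumulative-integral operator used by [patlakTransform()]; on noiseless
#' curves the downstream Patlak fit therefore recovers `kiTrue` to machine
#' precision. Optional additive Gaussian frame noise has
#' `SD = noiseSd * activity / duration` (a count-statistics proxy: noisier
#' where activity is high and frames are short); noisy activities are clipped
#' at zero.
#'
#' @param kiTrue true influx constant in 1/min (>= 0).
#' @param ref reference-region [TimeActivityCurve-class].
#' @param vRef distribution-volume intercept (> 0 unitless scale on the
#'   reference curve).
#' @param noiseSd fractional noise coefficient (0 = noiseless).
#' @param seed integer seed for the noise stream.
#' @return a [TimeActivityCurve-class] on the same frame grid as `ref`.
#' @export
#' @examples
#' ref <- simulateReferenceTac()
#' tis <- simulateTissueTac(0.012, ref)
simulateTissueTac <- function(kiTrue, ref, vRef = 1, noiseSd = 0, seed = NULL) {
  stopifnot(is(ref, "TimeActivityCurve"))
  if (!is.finite(kiTrue) || kiTrue < 0) stop("kiTrue must be >= 0")
  if (vRef <= 0) stop("vRef must be positive")
  mid <- frameMid(ref)
  a <- kiTrue * cumTrapz0(mid, activity(ref)) + vRef * activity(ref)
  if (noiseSd > 0) {
    dt <- frameEnd(ref) - frameStart(ref)
    a <- withSeed(seed, a + rnorm(length(a), 0, noiseSd * a / dt))
    a <- pmax(a, 0)
  }
  new("TimeActivityCurve", frameStart = frameStart(ref),
      frameEnd = frameEnd(ref), activity = a)
}

#' Simulate a 4-D dynamic volume from a Ki truth map
#'
#' Every voxel's time-activity curve follows the Patlak relation with that
#' voxel's true Ki (see [simulateTissueTac()]); a shared reference curve and
#' distribution volume apply everywhere. Voxels with Ki = 0 serve as
#' reference-like tissue.
#'
#' @param kiMap 3-D array of true influx constants (finite, >= 0).
#' @param ref reference [TimeActivityCurve-class].
#' @param vRef distribution-volume intercept.
#' @param noiseSd fractional frame-noise coefficient as in
#'   [simulateTissueTac()].
#' @param seed integer seed.
#' @param voxelSize numeric(3) voxel edge lengths in mm.
#' @return list with `volume` (4-D array, x y z frame), `truth` (a
#'   [KiVolume-class] holding `kiMap`), `frames` (timing data.frame), and
#'   `affine`.
#' @export
simulateDynamicVolume <- function(kiMap, ref, vRef = 1, noiseSd = 0,
                                  seed = NULL, voxelSize = c(4, 4, 5)) {
  stopifnot(is(ref, "TimeActivityCurve"), length(dim(kiMap)) == 3)
  if (any(!is.finite(kiMap))) stop("kiMap must be finite")
  if (any(kiMap < 0)) stop("kiMap must be non-negative")
  mid <- frameMid(ref)
  refA <- activity(ref)
  cint <- cumTrapz0(mid, refA)
  nvox <- length(kiMap)
  nf <- length(refA)
  # (voxel x frame) matrix: ki_v * C(t) + vRef * ref(t)
  A <- as.vector(kiMap) %o% cint + matrix(vRef * refA, nvox, nf, byrow = TRUE)
  if (noiseSd > 0) {
    dt <- frameEnd(ref) - frameStart(ref)
    sdM <- sweep(A, 2, dt, "/") * noiseSd
    A <- withSeed(seed, A + matrix(rnorm(nvox * nf), nvox, nf) * sdM)
    A <- pmax(A, 0)
  }
  affine <- diag(c(voxelSize, 1))
  list(volume = array(A, c(dim(kiMap), nf)),
       truth = new("KiVolume", values = kiMap, voxelSize = voxelSize,
                   affine = affine),
       frames = data.frame(frame_start_min = frameStart(ref),
                           frame_end_min = frameEnd(ref)),
       affine = affine)
}
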
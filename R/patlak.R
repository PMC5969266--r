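# Reference-region Patlak graphical analysis.
#
# For an irreversibly trapped tracer, plotting tissue(t)/ref(t) against
# "normalized time" Int_0^t ref(s) ds / ref(t) becomes linear once the
# reversible compartments equilibrate; the slope of the late-time line is the
# net influx constant Ki (1/min) and the intercept is scaled to the tracer
# distribution volume of the reference region.

#' Patlak transform of a tissue curve against a reference curve
#'
#' Computes the graphical-analysis coordinates at frame mid-times:
#' `x = CumInt(ref) / ref` (normalized time, minutes) and `y = tissue / ref`
#' (unitless), with the cumulative integral taken by the trapezoidal rule
#' anchored at zero activity at injection. Frames where the reference
#' activity is not positive are dropped with a warning.
#'
#' @param tissue tissue [TimeActivityCurve-class].
#' @param ref reference-region [TimeActivityCurve-class] on the identical
#'   frame grid.
#' @return data.frame with columns `mid` (frame mid-time, min), `x`, `y`.
#' @export
#' @examples
#' ref <- simulateReferenceTac()
#' pts <- patlakTransform(simulateTissueTac(0.012, ref), ref)
patlakTransform <- function(tissue, ref) {
  stopifnot(is(tissue, "TimeActivityCurve"), is(ref, "TimeActivityCurve"))
  if (!isTRUE(all.equal(frameStart(tissue), frameStart(ref))) ||
      !isTRUE(all.equal(frameEnd(tissue), frameEnd(ref))))
    stop("tissue and reference curves must share the frame grid")
  mid <- frameMid(ref)
  refA <- activity(ref)
  cint <- cumTrapz0(mid, refA)
  ok <- refA > 0
  if (!any(ok)) stop("reference activity is zero on all frames")
  if (!all(ok))
    warning(sum(!ok), " frame(s) dropped: reference activity not positive")
  data.frame(mid = mid[ok], x = cint[ok] / refA[ok],
             y = activity(tissue)[ok] / refA[ok])
}

#' Fit the Patlak line over a late-time window
#'
#' Ordinary least squares through the transformed points whose frame
#' mid-times fall inside `[tStart, tEnd]` minutes (default 24-89 min, the
#' window in which the [18F]DOPA plot is linear). The slope is reported as
#' Ki; the intercept is the distribution-volume scale.
#'
#' @param points data.frame from [patlakTransform()] (columns `mid`, `x`,
#'   `y`).
#' @param tStart,tEnd fit window in minutes.
#' @return a [PatlakFit-class].
#' @export
#' @examples
#' ref <- simulateReferenceTac()
#' fitPatlak(patlakTransform(simulateTissueTac(0.012, ref), ref))
fitPatlak <- function(points, tStart = 24, tEnd = 89) {
  stopifnot(all(c("mid", "x", "y") %in% names(points)))
  sel <- points$mid >= tStart & points$mid <= tEnd &
    is.finite(points$x) & is.finite(points$y)
  if (sum(sel) < 2) stop("need at least 2 points inside the fit window")
  x <- points$x[sel]
  y <- points$y[sel]
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate fit: no spread in normalized time")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  icpt <- mean(y) - slope * mean(x)
  res <- y - (icpt + slope * x)
  sst <- sum((y - mean(y))^2)
  rsq <- if (sst > 0) 1 - sum(res^2) / sst else
    if (sum(res^2) <= 1e-24) 1 else NA_real_
  new("PatlakFit", ki = slope, intercept = icpt, rSquared = rsq,
      nPoints = as.integer(sum(sel)), window = c(tStart, tEnd))
}

#' Voxel-wise Ki map from a 4-D dynamic volume
#'
#' Builds the reference curve as the unweighted mean time-activity curve over
#' the reference-mask voxels, Patlak-transforms every voxel against it, and
#' fits the windowed line everywhere in one vectorized pass (the normalized
#' time axis is shared by all voxels). Voxels with non-finite data get the
#' NaN sentinel and are counted.
#'
#' @param dynamic 4-D array (x, y, z, frame).
#' @param frames frame-timing data.frame (`frame_start_min`,
#'   `frame_end_min`), matching the 4th dimension.
#' @param refMask [RoiMask-class] of reference-region voxels (e.g.
#'   cerebellum), non-empty.
#' @param tStart,tEnd Patlak fit window in minutes (default 24-89).
#' @param voxelSize numeric(3) voxel edges in mm.
#' @param affine optional 4x4 grid-to-world matrix (defaults to a scaled
#'   identity from `voxelSize`).
#' @return a [KiVolume-class]; attribute `nNonFittable` counts sentinel
#'   voxels and attribute `intercepts` holds the per-voxel intercept map.
#' @export
kiImage <- function(dynamic, frames, refMask, tStart = 24, tEnd = 89,
                    voxelSize = c(4, 4, 5), affine = NULL) {
  stopifnot(length(dim(dynamic)) == 4, is(refMask, "RoiMask"))
  d <- dim(dynamic)
  if (!all(dim(roiMask(refMask)) == d[1:3]))
    stop("reference mask shape does not match the dynamic volume")
  if (nrow(frames) != d[4])
    stop("frame table does not match the 4th dimension")
  msk <- as.vector(roiMask(refMask))
  if (!any(msk)) stop("reference mask is empty")
  nf <- d[4]
  Y <- matrix(dynamic, ncol = nf)        # voxels x frames
  refA <- colMeans(Y[msk, , drop = FALSE])
  mid <- (frames$frame_start_min + frames$frame_end_min) / 2
  if (all(refA <= 0)) stop("reference activity is zero on all frames")
  cint <- cumTrapz0(mid, refA)
  sel <- mid >= tStart & mid <= tEnd & refA > 0
  if (sum(sel) < 2) stop("need at least 2 frames inside the fit window")
  x <- (cint / refA)[sel]
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  Yw <- sweep(Y[, sel, drop = FALSE], 2, refA[sel], "/")
  ybar <- rowMeans(Yw)
  slope <- as.vector(Yw %*% xc) / sxx
  icpt <- ybar - slope * mean(x)
  bad <- !is.finite(slope)
  slope[bad] <- NaN
  out <- new("KiVolume", values = array(slope, d[1:3]),
             voxelSize = voxelSize,
             affine = affine %||% diag(c(voxelSize, 1)))
  attr(out@values, "dimnames") <- NULL
  attr(out, "nNonFittable") <- sum(bad)
  attr(out, "intercepts") <- array(icpt, d[1:3])
  out
}

#' Threshold a Ki template into a striatal mask
#'
#' Retains the template voxels whose value is at least `k` standard
#' deviations above the template mean (mean and SD over all finite template
#' voxels) -- with the default k = 3 on a whole-brain [18F]DOPA Ki template
#' this approximates the anatomical boundaries of the striatum, where
#' tracer trapping is maximal.
#'
#' @param template a [KiVolume-class] template.
#' @param k number of standard deviations above the mean (default 3).
#' @return a [RoiMask-class] aligned with the template.
#' @export
makeTemplateMask <- function(template, k = 3) {
  stopifnot(is(template, "KiVolume"))
  v <- template@values
  fin <- is.finite(v)
  m <- mean(v[fin])
  s <- stats::sd(v[fin])
  if (!is.finite(s) || s == 0)
    stop("template has zero variance: the k-SD criterion is undefined")
  mk <- array(fin & v >= m + k * s, dim(v))
  new("RoiMask", mask = mk, affine = template@affine)
}

#' Summarize Ki over a region of interest
#'
#' Mean and SD of the finite Ki values inside the mask; masked voxels holding
#' the non-fittable sentinel are excluded and counted.
#'
#' @param kiVol a [KiVolume-class].
#' @param mask a [RoiMask-class] of identical shape.
#' @return list: `mean`, `sd`, `nVoxels` (finite voxels used), `nExcluded`
#'   (masked but non-finite).
#' @export
extractRoi <- function(kiVol, mask) {
  stopifnot(is(kiVol, "KiVolume"), is(mask, "RoiMask"))
  if (!all(dim(kiVol@values) == dim(roiMask(mask))))
    stop("mask and image shapes differ")
  if (!any(roiMask(mask))) stop("mask is empty")
  vals <- kiVol@values[roiMask(mask)]
  fin <- is.finite(vals)
  list(mean = mean(vals[fin]), sd = stats::sd(vals[fin]),
       nVoxels = sum(fin), nExcluded = sum(!fin))
}
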
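# Voxel-wise regression of Ki maps on a subject-level predictor with
# family-wise error control by the permutation distribution of the maximum
# |t| statistic -- an assumption-light alternative to random-field theory.

#' Voxel-wise regression with permutation max-|t| FWE correction
#'
#' Fits, at every masked voxel, the simple regression of the subjects' Ki
#' values on the predictor (e.g. sEBR) and converts the slope to a t
#' statistic. Family-wise error-adjusted p-values come from the permutation
#' distribution of the maximum |t| over the mask: the predictor is permuted
#' across subjects B times and each voxel's |t| is referred to the maxima,
#' `p_FWE = (1 + #{max|t|_b >= |t|}) / (B + 1)`.
#'
#' @param kiStack list of [KiVolume-class] objects (one per subject, same
#'   grid) or a 4-D array (x, y, z, subject).
#' @param predictor numeric vector, one value per subject.
#' @param mask [RoiMask-class] restricting the analysis (e.g. the striatum).
#' @param B number of permutations (default 1000; < 100 draws a warning).
#' @param seed integer seed for the permutation stream.
#' @param alpha significance level used for `nSignificant` (default 0.05).
#' @return list of class `voxelwiseResult`: `tMap` and `fweMap` (3-D arrays,
#'   NA outside the mask), `peak` (list: `index` 1-based voxel triple,
#'   `index0` 0-based, `world` coordinates from the affine, `t`, `fweP`),
#'   `nSignificant`, `B`, `n`.
#' @export
voxelwiseRegression <- function(kiStack, predictor, mask, B = 1000,
                                seed = NULL, alpha = 0.05) {
  stopifnot(is(mask, "RoiMask"))
  if (is.list(kiStack)) {
    stopifnot(all(vapply(kiStack, is, logical(1), "KiVolume")))
    arr <- vapply(kiStack, function(k) k@values,
                  array(0, dim(kiStack[[1]]@values)))
    affine <- kiStack[[1]]@affine
  } else {
    stopifnot(length(dim(kiStack)) == 4)
    arr <- kiStack
    affine <- mask@affine
  }
  d <- dim(arr)
  nsub <- d[4]
  if (length(predictor) != nsub)
    stop("predictor length must equal the number of subjects")
  if (stats::sd(predictor) == 0) stop("constant predictor")
  if (nsub < 4) stop("need at least 4 subjects")
  if (B < 100) warning("fewer than 100 permutations: p-values are coarse")
  if (!all(dim(roiMask(mask)) == d[1:3]))
    stop("mask shape does not match the Ki stack")
  msk <- which(as.vector(roiMask(mask)))
  if (!length(msk)) stop("mask is empty")
  Y <- matrix(arr, ncol = nsub)[msk, , drop = FALSE]   # voxels x subjects
  ok <- rowSums(!is.finite(Y)) == 0
  df <- nsub - 2
  r2t <- function(rv) rv * sqrt(df / pmax(1 - rv^2, 1e-12))
  corWith <- function(xs) {
    yc <- Y[ok, , drop = FALSE] - rowMeans(Y[ok, , drop = FALSE])
    ysd <- sqrt(rowSums(yc^2))
    as.vector(yc %*% xs) / pmax(ysd, 1e-300)
  }
  std <- function(v) {
    v <- v - mean(v)
    v / sqrt(sum(v^2))
  }
  tObs <- rep(NA_real_, length(msk))
  tOk <- r2t(corWith(std(predictor)))
  tObs[ok] <- tOk
  # permutation null of the maximum |t| over the mask
  P <- withSeed(seed, vapply(seq_len(B),
                             function(b) std(sample(predictor)),
                             numeric(nsub)))
  yc <- Y[ok, , drop = FALSE] - rowMeans(Y[ok, , drop = FALSE])
  ysd <- sqrt(rowSums(yc^2))
  Rmat <- (yc %*% P) / pmax(ysd, 1e-300)       # voxels x B correlations
  maxT <- apply(abs(r2t(Rmat)), 2, max)
  fwe <- rep(NA_real_, length(msk))
  fwe[ok] <- vapply(abs(tOk), function(tv) (1 + sum(maxT >= tv)) / (B + 1),
                    numeric(1))
  tMap <- array(NA_real_, d[1:3])
  fweMap <- array(NA_real_, d[1:3])
  tMap[msk] <- tObs
  fweMap[msk] <- fwe
  pk <- msk[which.max(abs(tObs))]
  ijk <- arrayInd(pk, d[1:3])[1, ]
  world <- as.vector(affine %*% c(ijk - 1, 1))[1:3]
  structure(list(tMap = tMap, fweMap = fweMap,
                 peak = list(index = ijk, index0 = ijk - 1L, world = world,
                             t = tMap[pk], fweP = fweMap[pk]),
                 nSignificant = sum(fwe <= alpha, na.rm = TRUE),
                 B = B, n = nsub),
            class = "voxelwiseResult")
}

#' @export
print.voxelwiseResult <- function(x, ...) {
  cat(sprintf(
    "Voxel-wise regression (n = %d, %d permutations): peak t = %.3f at voxel (%d, %d, %d), FWE p = %.4g; %d voxel(s) significant\n",
    x$n, x$B, x$peak$t, x$peak$index[1], x$peak$index[2], x$peak$index[3],
    x$peak$fweP, x$nSignificant))
  invisible(x)
}
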
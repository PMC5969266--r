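# Independent brute-force oracles used across tests.

# Spearman rho as explicit Pearson formula applied to average ranks,
# written out rather than via cor().
bruteSpearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Cronbach's alpha for two raters via the covariance identity
# alpha = 4 cov(a, b) / var(a + b).
bruteAlpha2 <- function(a, b) 4 * cov(a, b) / var(a + b)

# Greedy one-to-one matching of detected onsets to planted onsets within a
# tolerance (seconds); returns counts for precision/recall.
matchOnsets <- function(detected, planted, tol = 0.05) {
  used <- rep(FALSE, length(planted))
  tp <- 0L
  for (d in detected) {
    j <- which(!used & abs(planted - d) <= tol)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = length(detected) - tp, fn = length(planted) - tp)
}

f1Score <- function(m) {
  if (m$tp == 0) return(0)
  prec <- m$tp / (m$tp + m$fp)
  rec <- m$tp / (m$tp + m$fn)
  2 * prec * rec / (prec + rec)
}

# A small all-TRUE mask on a given grid.
fullMask <- function(d, affine = diag(4))
  new("RoiMask", mask = array(TRUE, d), affine = affine)
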
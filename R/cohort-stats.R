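# Frequentist cohort statistics: the normality gate that motivates rank
# correlation, Spearman's rho with exact small-sample p-values, and the
# bootstrapped partial regression of Ki on sEBR with covariates.

#' Normality gate for choosing rank-based correlation
#'
#' One-sample Kolmogorov-Smirnov test of the values against a normal
#' distribution with the sample mean and SD. A significant departure
#' (p < 0.05) flags the variable for rank-based (Spearman) analysis.
#'
#' @param values numeric vector (n >= 4).
#' @param alpha significance level of the gate (default 0.05).
#' @return list: `useRank` (logical), `pValue`, `statistic`.
#' @export
#' @examples
#' normalityGate(rexp(50))$useRank
normalityGate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("need at least 4 finite values")
  if (stats::sd(values) == 0) {
    warning("constant input: normality undefined, falling back to ranks")
    return(list(useRank = TRUE, pValue = NA_real_, statistic = NA_real_))
  }
  ks <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), stats::sd(values)))
  list(useRank = ks$p.value < alpha, pValue = ks$p.value,
       statistic = unname(ks$statistic))
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' rho is the Pearson correlation of the (average, i.e. tie-midranked) ranks.
#' The p-value is exact for n <= 9 without ties and uses the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise; two-sided by default.
#'
#' @param x,y numeric vectors of equal length (n >= 4).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return list of class `correlationResult`: `rho`, `pValue`, `n`,
#'   `method` ("exact" or "t-approximation").
#' @export
#' @examples
#' spearmanCor(1:5, c(2, 1, 4, 3, 5))$rho  # 0.8
spearmanCor <- function(x, y, alternative = "two.sided") {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("need at least 4 pairs")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero variance in ranks: correlation undefined")
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- n <= 9 && !ties
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact,
                    alternative = alternative))
  structure(list(rho = rho, pValue = ct$p.value, n = n,
                 method = if (exact) "exact" else "t-approximation"),
            class = "correlationResult")
}

#' @export
print.correlationResult <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.4g (n = %d, %s)\n",
              x$rho, x$pValue, x$n, x$method))
  invisible(x)
}

# slope of `predictor` in an OLS fit of outcome ~ predictor + covariates,
# via QR on the design matrix; NA if the design is rank-deficient.
partialSlope <- function(X, yv, j) {
  q <- qr(X)
  if (q$rank < ncol(X)) return(NA_real_)
  qr.coef(q, yv)[j]
}

#' Partial regression of Ki on sEBR with bootstrapped beta
#'
#' OLS slope of the predictor in the multiple regression of the outcome on
#' predictor plus covariates; the uncertainty of the slope is assessed by a
#' nonparametric bootstrap over subjects (row resampling): percentile
#' confidence interval and a two-sided bootstrap p-value
#' `2 * min(P(b* <= 0), P(b* >= 0))` with add-one smoothing.
#'
#' @param table cohort data.frame (columns named in `outcome`, `predictor`,
#'   `covariates`).
#' @param outcome,predictor column names (defaults "ki", "sebr").
#' @param covariates character vector of covariate columns (default
#'   c("age", "group"); character/factor columns are expanded via
#'   `model.matrix`). Use `character()` for a simple regression.
#' @param reps bootstrap replicates (default 2000).
#' @param seed integer seed for the resampling stream.
#' @param level confidence level of the percentile interval.
#' @return list of class `partialRegressionResult`: `beta`, `ci`, `pValue`,
#'   `reps` (effective replicates), `nDropped` (singular resamples), `n`.
#' @export
bootstrapPartialRegression <- function(table, outcome = "ki",
                                       predictor = "sebr",
                                       covariates = c("age", "group"),
                                       reps = 2000, seed = NULL,
                                       level = 0.95) {
  stopifnot(all(c(outcome, predictor, covariates) %in% names(table)))
  n <- nrow(table)
  if (n <= length(covariates) + 2)
    stop("need more subjects than regressors plus one")
  fml <- stats::reformulate(c(predictor, covariates))
  mf <- stats::model.frame(fml, data = table)
  X <- stats::model.matrix(fml, mf)
  yv <- table[[outcome]]
  j <- match(predictor, colnames(X))
  beta <- partialSlope(X, yv, j)
  if (is.na(beta)) stop("singular design matrix (constant covariate?)")
  bstar <- withSeed(seed, vapply(seq_len(reps), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    partialSlope(X[idx, , drop = FALSE], yv[idx], j)
  }, numeric(1)))
  dropped <- sum(is.na(bstar))
  bstar <- bstar[!is.na(bstar)]
  R <- length(bstar)
  if (R < reps / 2) stop("too many singular bootstrap resamples")
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(bstar, c(a, 1 - a), type = 7))
  pv <- min(1, 2 * min((1 + sum(bstar <= 0)) / (R + 1),
                       (1 + sum(bstar >= 0)) / (R + 1)))
  structure(list(beta = unname(beta), ci = ci, pValue = pv, reps = R,
                 nDropped = dropped, n = n, predictor = predictor,
                 covariates = covariates),
            class = "partialRegressionResult")
}

#' @export
print.partialRegressionResult <- function(x, ...) {
  cat(sprintf(
    "Partial regression: beta[%s] = %.4g (%.0f%% bootstrap CI %.4g to %.4g, p = %.3g, %d reps)\n",
    x$predictor, x$beta, 95, x$ci[1], x$ci[2], x$pValue, x$reps))
  invisible(x)
}
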
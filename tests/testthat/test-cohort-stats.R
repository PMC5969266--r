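test_that("the normality gate passes normal samples and flags skewed ones", {
  set.seed(4)
  gN <- normalityGate(rnorm(5000))
  expect_false(gN$useRank)
  gE <- normalityGate(rexp(5000))
  expect_true(gE$useRank)
  expect_lt(gE$pValue, 1e-6)
  expect_warning(g0 <- normalityGate(rep(1, 10)), "constant")
  expect_true(g0$useRank)
})

test_that("Spearman rho matches the brute-force rank-then-Pearson oracle", {
  expect_equal(spearmanCor(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  x <- 1:8
  expect_equal(spearmanCor(x, x^3)$rho, 1)          # monotone map
  expect_equal(spearmanCor(x, rev(x))$rho, -1)
  set.seed(7)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    a <- rnorm(n)
    b <- if (i %% 3 == 0) sample(round(rnorm(n)), n, TRUE) else rnorm(n)
    expect_equal(spearmanCor(a, b)$rho, bruteSpearman(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Spearman p-values are exact for small n and approximate above", {
  s5 <- spearmanCor(1:5, c(2, 1, 4, 3, 5))
  expect_equal(s5$method, "exact")
  # exact two-sided tail of the permutation distribution of rho at n = 5
  ref <- {
    pm <- as.matrix(expand.grid(rep(list(1:5), 5)))
    pm <- pm[apply(pm, 1, function(r) length(unique(r)) == 5), ]
    rhos <- apply(pm, 1, function(p) bruteSpearman(1:5, p))
    mean(abs(rhos) >= abs(s5$rho) - 1e-12)
  }
  expect_equal(s5$pValue, ref, tolerance = 1e-10)
  s20 <- spearmanCor(rnorm(20), rnorm(20))
  expect_equal(s20$method, "t-approximation")
  expect_error(spearmanCor(rep(1, 6), 1:6), "zero variance")
  expect_error(spearmanCor(1:3, 3:1), "at least 4")
})

test_that("partial regression reduces to the simple slope without covariates", {
  coh <- simulateCohort(40, -0.4, seed = 12)
  simple <- unname(coef(lm(ki ~ sebr, coh))["sebr"])
  b <- bootstrapPartialRegression(coh, covariates = character(), reps = 200,
                                  seed = 1)
  expect_equal(b$beta, simple, tolerance = 1e-12)
  expect_true(b$ci[1] <= b$beta && b$beta <= b$ci[2])
})

test_that("an orthogonal covariate leaves the slope unchanged", {
  coh <- simulateCohort(50, -0.4, seed = 13)
  # residualize a random covariate against predictor, outcome and intercept
  z <- rnorm(50)
  coh$orth <- resid(lm(z ~ sebr + ki, coh))
  simple <- unname(coef(lm(ki ~ sebr, coh))["sebr"])
  b <- bootstrapPartialRegression(coh, covariates = "orth", reps = 100,
                                  seed = 2)
  expect_equal(b$beta, simple, tolerance = 1e-10)
})

test_that("singular designs are rejected", {
  coh <- simulateCohort(20, 0, seed = 14)
  coh$const <- 1
  expect_error(bootstrapPartialRegression(coh, covariates = "const"),
               "singular")
})

test_that("bootstrap intervals cover a known partial slope at the right rate", {
  hits <- vapply(1:120, function(s) {
    n <- 80
    set.seed(3000 + s)
    x <- rnorm(n)
    z <- rnorm(n)
    grp <- rep(c("a", "b"), n / 2)
    y <- -2 * x + 0.5 * z + (grp == "b") + rnorm(n)
    tab <- data.frame(ki = y, sebr = x, age = z, group = grp)
    b <- bootstrapPartialRegression(tab, reps = 400, seed = s)
    b$ci[1] <= -2 && -2 <= b$ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.86)
  expect_lte(mean(hits), 0.995)
})
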
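test_that("Spearman rho matches hand-ranked cases and the base-R oracle", {
  expect_equal(spearmanRho(1:7, 1:7)$rho, 1)
  expect_equal(spearmanRho(1:7, 7:1)$rho, -1)
  expect_equal(spearmanRho(1:5, c(1, 3, 2, 5, 4))$rho, 0.8)

  set.seed(31)
  x <- round(rnorm(20), 1)  # rounding forces ties
  y <- round(x + rnorm(20), 1)
  ours <- spearmanRho(x, y)
  oracle <- suppressWarnings(cor.test(x, y, method = "spearman",
                                      exact = FALSE))
  expect_equal(ours$rho, unname(oracle$estimate), tolerance = 1e-12)
  expect_equal(ours$p, oracle$p.value, tolerance = 1e-9)

  one <- spearmanRho(x, y, tail = "greater")
  expect_equal(one$p, ours$p / 2, tolerance = 1e-12)
  expect_error(spearmanRho(rep(1, 5), 1:5), "constant")
})

test_that("Spearman rho is invariant to strictly monotone transforms", {
  set.seed(32)
  x <- rnorm(25); y <- rnorm(25)
  base <- spearmanRho(x, y)$rho
  expect_equal(spearmanRho(exp(x), y)$rho, base)
  expect_equal(spearmanRho(x, y^3 + 2 * y)$rho, base)
})

test_that("partial Spearman reduces to Spearman with no covariates and
           matches an explicit normal-equations oracle", {
  set.seed(33)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(partialSpearman(x, y, NULL)$rho, spearmanRho(x, y)$rho)

  # fixed 8-point dataset with a shared driver z
  z <- c(1.2, -0.4, 0.8, 2.1, -1.7, 0.3, -0.9, 1.5)
  x8 <- c(1.5, -0.1, 0.2, 2.6, -1.1, 0.9, -1.4, 1.1)
  y8 <- c(0.8, -0.9, 1.2, 1.9, -2.0, -0.2, -0.5, 2.0)
  ours <- partialSpearman(x8, y8, cbind(z = z))

  # oracle: rank everything, solve the two residual regressions by explicit
  # normal equations, correlate the residuals
  rx <- rank(x8); ry <- rank(y8); rz <- rank(z)
  D <- cbind(1, rz)
  bx <- solve(t(D) %*% D, t(D) %*% rx)
  by <- solve(t(D) %*% D, t(D) %*% ry)
  ex <- rx - D %*% bx; ey <- ry - D %*% by
  rhoOracle <- sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
  expect_equal(ours$rho, rhoOracle, tolerance = 1e-12)
  expect_equal(ours$df, 8L - 1L - 2L)

  expect_error(partialSpearman(x8, y8, cbind(y8)), "perfectly explained")
  expect_error(partialSpearman(x8, y8, cbind(z, z)), "collinear")
})

test_that("partialling a jointly independent covariate keeps the nominal
           rejection rate", {
  set.seed(34)
  rej <- mean(replicate(400, {
    x <- rnorm(34); y <- rnorm(34); Z <- matrix(rnorm(34 * 2), 34)
    partialSpearman(x, y, Z)$p < 0.05
  }))
  expect_lte(rej, 0.05 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("Holm and Bonferroni match hand-worked vectors and stay ordered", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(adjustPvalues(p, "holm"), c(0.03, 0.04, 0.04))
  expect_equal(adjustPvalues(p, "bonferroni"), c(0.03, 0.06, 0.09))
  expect_equal(adjustPvalues(0.2, "holm"), 0.2)
  expect_equal(adjustPvalues(0.2, "bonferroni"), 0.2)
  expect_error(adjustPvalues(c(0.5, 1.2), "holm"), "\\[0, 1\\]")

  set.seed(35)
  for (i in 1:20) {
    p <- runif(15)
    h <- adjustPvalues(p, "holm")
    b <- adjustPvalues(p, "bonferroni")
    expect_true(all(h <= b + 1e-12))
    expect_true(all(h >= p - 1e-12))
    # monotonicity: raising one raw p never lowers any adjusted p
    p2 <- p; j <- sample(15, 1)
    p2[j] <- min(1, p[j] + runif(1, 0, 1 - p[j]))
    expect_true(all(adjustPvalues(p2, "holm") >= h - 1e-12))
  }
})

test_that("Cronbach's alpha matches the closed form and its degenerate cases", {
  m <- cbind(r1 = c(1, 2, 3), r2 = c(1, 2, 3), r3 = c(1, 2, 3))
  expect_equal(cronbachAlpha(m), 1)

  r1 <- c(1, 2, 3); r2 <- c(1.2, 1.8, 3.4)
  m2 <- cbind(r1, r2)
  k <- 2
  alphaHand <- k / (k - 1) * (1 - (var(r1) + var(r2)) / var(r1 + r2))
  expect_equal(cronbachAlpha(m2), alphaHand, tolerance = 1e-12)

  expect_error(cronbachAlpha(matrix(1:3, 3, 1)), "2 raters")
  expect_error(cronbachAlpha(matrix(1, 3, 2)), "zero variance")

  set.seed(36)
  alphas <- replicate(300, cronbachAlpha(
    cbind(sample(1:50), sample(1:50), sample(1:50))))
  expect_lt(abs(mean(alphas)), 0.1)  # independent raters: alpha centers on 0
})

test_that("hierarchical R2 matches an explicit OLS oracle and its identities", {
  set.seed(37)
  f <- cbind(f1 = rnorm(6), f2 = rnorm(6))
  resp <- c(2.0, -1.5, 0.7, 1.1, -0.3, 0.9)
  vp <- hierarchicalR2(f, resp, first = "f1", responseLabel = "toy")

  r2of <- function(X, y) {
    D <- cbind(1, X)
    b <- solve(t(D) %*% D, t(D) %*% y)
    1 - sum((y - D %*% b)^2) / sum((y - mean(y))^2)
  }
  expect_equal(vp@r2First, r2of(f[, "f1", drop = FALSE], resp),
               tolerance = 1e-10)
  expect_equal(vp@r2Total, r2of(f, resp), tolerance = 1e-10)
  expect_equal(vp@r2Increment, vp@r2Total - vp@r2First, tolerance = 1e-12)

  # order-dependence of increments, order-invariance of the total
  vp2 <- hierarchicalR2(f, resp, first = "f2")
  expect_equal(vp2@r2Total, vp@r2Total, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(vp2@r2First, vp@r2First)))

  # response equal to the first factor
  vpx <- hierarchicalR2(f, f[, "f1"], first = "f1")
  expect_equal(vpx@r2First, 1, tolerance = 1e-10)
  expect_equal(vpx@r2Increment, 0, tolerance = 1e-10)

  # response orthogonalized against both predictors and the intercept
  y <- rnorm(6)
  yo <- residuals(lm(y ~ f))
  expect_lt(hierarchicalR2(f, yo)@r2Total, 1e-8)

  expect_error(hierarchicalR2(cbind(f1 = f[, 1], f2 = 2 * f[, 1]), resp),
               "collinear")
})

test_that("correlation reports carry the full family and its correction", {
  set.seed(38)
  X <- matrix(rnorm(20 * 3), 20); colnames(X) <- c("a", "b", "c")
  Y <- matrix(rnorm(20 * 2), 20); colnames(Y) <- c("u", "v")
  rep <- correlationMatrix(X, Y, correction = "holm")
  e <- reportEntries(rep)
  expect_equal(nrow(e), 6L)
  expect_equal(e$p_adjusted, adjustPvalues(e$p, "holm"))
  expect_true(all(e$p_adjusted >= e$p))

  one <- correlationMatrix(X[, 1, drop = FALSE], X[, 1, drop = FALSE])
  expect_equal(reportEntries(one)$rho, 1)
})
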
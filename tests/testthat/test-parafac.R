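test_that("fiber standardization matches hand computation and flags errors", {
  stim <- StimulusSet(c("a", "b", "c"), "music")
  scales <- bipolarScales("happy/sad")
  vals <- array(c(1, 2, 3), dim = c(3, 1, 1))
  t1 <- standardizeTensor(RatingsTensor(vals, stim, scales, "k1"))
  expect_equal(unname(ratingValues(t1)[, 1, 1]), c(-1, 0, 1))
  expect_true(isStandardized(t1))
  expect_error(standardizeTensor(t1), "already standardized")

  pop <- standardizeTensor(RatingsTensor(vals, stim, scales, "k1"),
                           sdType = "population")
  expect_equal(unname(ratingValues(pop)[, 1, 1]),
               (c(1, 2, 3) - 2) / sqrt(2 / 3))

  const <- RatingsTensor(array(5, dim = c(3, 1, 1)), stim, scales, "k1")
  expect_error(standardizeTensor(const), "zero-variance.*happy/sad.*k1")

  # an already standard-normal fiber passes through unchanged
  z <- c(-1, 0, 1)
  t2 <- standardizeTensor(RatingsTensor(array(z, c(3, 1, 1)), stim, scales,
                                        "k1"))
  expect_equal(unname(ratingValues(t2)[, 1, 1]), z, tolerance = 1e-12)
})

test_that("exact low-rank tensors are recovered to numerical precision", {
  set.seed(41)
  a <- rnorm(9); b <- runif(5); cc <- runif(4)
  Z1 <- a %o% b %o% cc
  m1 <- fitCp(Z1, 1, nStarts = 3L, seed = 1L)
  expect_lte(residualSS(m1) / sum(Z1^2), 1e-8)
  expect_gte(tuckerCongruence(factorMatrix(m1, "stimuli"), cbind(a))[1L],
             0.999)

  # rank-2 with orthogonal planted factor matrices
  A <- qr.Q(qr(matrix(rnorm(18), 9)))[, 1:2]
  B <- qr.Q(qr(matrix(rnorm(10), 5)))[, 1:2]
  C <- qr.Q(qr(matrix(rnorm(8), 4)))[, 1:2]
  Z2 <- trilinearTensor(A, B, C)
  m2 <- fitCp(Z2, 2, nStarts = 5L, seed = 2L)
  expect_lte(residualSS(m2) / sum(Z2^2), 1e-8)
  expect_true(all(tuckerCongruence(factorMatrix(m2, "stimuli"), A) >= 0.999))
  expect_true(all(tuckerCongruence(factorMatrix(m2, "scales"), B) >= 0.999))
})

test_that("fitting is deterministic given the seed and validates inputs", {
  set.seed(42)
  Z <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  m1 <- fitCp(Z, 2, nStarts = 3L, seed = 7L)
  m2 <- fitCp(Z, 2, nStarts = 3L, seed = 7L)
  expect_identical(factorMatrix(m1, "stimuli"), factorMatrix(m2, "stimuli"))
  expect_identical(residualSS(m1), residualSS(m2))

  expect_error(fitCp(Z, 5), "exceeds a mode")
  Zb <- Z; Zb[1] <- NA
  expect_error(fitCp(Zb, 2), "non-finite")
})

test_that("ALS never increases the SSE within a start and the retained start
           is the best", {
  set.seed(43)
  Z <- array(rnorm(8 * 6 * 5), c(8, 6, 5))
  m <- fitCp(Z, 3, nStarts = 6L, seed = 11L)
  expect_true(all(diff(sseTrace(m)) <= 1e-8 * sum(Z^2)))
  singles <- sapply(0:5, function(s)
    varianceExplained(fitCp(Z, 3, nStarts = 1L, seed = 11L + s)))
  expect_gte(varianceExplained(m) + 1e-12, max(singles))
})

test_that("the B/C normalization convention holds", {
  set.seed(44)
  Z <- array(rnorm(7 * 5 * 4), c(7, 5, 4))
  m <- fitCp(Z, 2, nStarts = 3L, seed = 3L)
  expect_equal(colSums(factorMatrix(m, "scales")^2), c(factor1 = 1,
                                                       factor2 = 1),
               tolerance = 1e-9)
  expect_equal(colSums(factorMatrix(m, "subjects")^2), c(factor1 = 1,
                                                         factor2 = 1),
               tolerance = 1e-9)
  expect_gte(varianceExplained(m), 0)
  expect_lte(varianceExplained(m), 1)
})

test_that("CORCONDIA is 100 on exact-rank fits and matches the
           normal-equations oracle elsewhere", {
  set.seed(45)
  A <- matrix(rnorm(16), 8); B <- matrix(rnorm(10), 5)
  C <- matrix(rnorm(8), 4)
  Z <- trilinearTensor(A, B, C)
  m <- fitCp(Z, 2, nStarts = 5L, seed = 5L)
  expect_equal(corcondia(Z, m), 100, tolerance = 1e-6)

  # over-factoring: a rank-2 truth with 10% noise deliberately fit at
  # R = 3 -> the extra factor chases noise and core consistency collapses
  set.seed(204)
  A2 <- matrix(rnorm(20), 10); B2 <- matrix(rnorm(12), 6)
  C2 <- matrix(rnorm(10), 5)
  Zt <- trilinearTensor(A2, B2, C2)
  Zt <- Zt + array(rnorm(300, sd = 0.1 * sqrt(sum(Zt^2) / 300)), c(10, 6, 5))
  m1 <- fitCp(Zt, 3, nStarts = 6L, seed = 6L)
  cc <- corcondia(Zt, m1)
  expect_lt(cc, 95)
  expect_equal(cc, corcondiaOracle(Zt, m1), tolerance = 1e-6)

  # R = 1 fits score 100 on any tensor (single core element = LS scale)
  Zr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  mr <- fitCp(Zr, 1, nStarts = 3L, seed = 7L)
  expect_equal(corcondia(Zr, mr), 100, tolerance = 1e-6)
  expect_equal(corcondia(Zr, mr), corcondiaOracle(Zr, mr), tolerance = 1e-6)
})

test_that("the scree table tracks capacity and flags the planted rank", {
  set.seed(46)
  A <- matrix(rnorm(20), 10); B <- matrix(rnorm(12), 6)
  C <- matrix(rnorm(10), 5)
  Z <- trilinearTensor(A, B, C) + array(rnorm(300, sd = 1e-4), c(10, 6, 5))
  tab <- screeCp(Z, Rrange = 1:4, nStarts = 5L, seed = 8L)
  expect_equal(tab$R, 1:4)
  expect_true(all(diff(tab$varianceExplained) >= -1e-8))
  expect_gte(tab$varianceExplained[2L], 0.999)
  expect_gte(tab$corcondia[2L], 99)
  expect_lt(tab$corcondia[3L], 50)  # over-factoring collapses consistency

  empty <- screeCp(Z, Rrange = integer(0))
  expect_equal(nrow(empty), 0L)
})

test_that("alignment fixes orientation without touching the fit", {
  b <- smallBundle(16L)
  joint <- jointEmotionTensor(b$colorEmotion, b$musicEmotion)
  std <- standardizeTensor(joint$tensor)
  m <- fitCp(std, 2, nStarts = 4L, seed = 9L)
  anchors <- c("agitated/calm" = 1L, "happy/sad" = 2L)
  al <- alignFactors(m, anchors)
  expect_gte(factorMatrix(al, "scales")["agitated/calm", 1L], 0)
  expect_gte(factorMatrix(al, "scales")["happy/sad", 2L], 0)
  expect_identical(residualSS(al), residualSS(m))

  # idempotence
  al2 <- alignFactors(al, anchors)
  expect_identical(factorMatrix(al2, "stimuli"), factorMatrix(al, "stimuli"))

  # a sign flip and a column swap are undone exactly, reconstruction intact
  tweaked <- al
  tweaked@A <- al@A[, c(2L, 1L)] %*% diag(c(-1, 1))
  tweaked@B <- al@B[, c(2L, 1L)] %*% diag(c(-1, 1))
  tweaked@C <- al@C[, c(2L, 1L)]
  rownames(tweaked@B) <- rownames(al@B)
  rownames(tweaked@A) <- rownames(al@A)
  fixed <- alignFactors(tweaked, anchors)
  expect_equal(abs(unname(factorMatrix(fixed, "stimuli"))),
               abs(unname(factorMatrix(al, "stimuli"))), tolerance = 1e-9)
  expect_true(all(tuckerCongruence(factorMatrix(fixed, "stimuli"),
                                   factorMatrix(al, "stimuli")) >= 1 - 1e-9))

  expect_error(alignFactors(m, c(a = 1, a = 2)), "contradictory|anchored")
  expect_error(alignFactors(m, c("nope/scale" = 1L)), "not in the model")
})

test_that("joint stimulus blocks split and restack exactly", {
  b <- generateBundle(analysisConfig(synthetic = list(seed = 17L)))
  fit <- jointAffectFit(b)
  expect_equal(nrow(factorMatrix(fit$model, "stimuli")), 37L + 34L)
  blocks <- splitJointScores(fit$model, fit$index)
  expect_equal(nrow(blocks$color), 37L)
  expect_equal(nrow(blocks$music), 34L)
  expect_equal(unname(rbind(blocks$color, blocks$music)),
               unname(factorMatrix(fit$model, "stimuli")))

  bad <- JointStimulusIndex(10L, 20L)
  expect_error(splitJointScores(fit$model, bad), "partition")
})

test_that("Tucker congruence is invariant to sign and permutation", {
  set.seed(47)
  M <- matrix(rnorm(30), 10, 3)
  expect_equal(unname(tuckerCongruence(M, M)), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(tuckerCongruence(M, -M)), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  Mp <- M[, c(3, 1, 2)] + matrix(rnorm(30, sd = 0.01), 10, 3)
  expect_true(all(tuckerCongruence(M, Mp) >= 0.99))
  Mz <- M; Mz[, 2] <- 0
  expect_error(tuckerCongruence(M, Mz), "zero-norm")
})

test_that("joint and single-modality fits share scale loadings on synthetic
           data with common loadings", {
  cfg <- smallConfig(18L, noiseSd = 8, nSubjects = 10L)
  b <- generateBundle(cfg)
  fitJoint <- fitCp(standardizeTensor(jointEmotionTensor(
    b$colorEmotion, b$musicEmotion)$tensor), 2, nStarts = 4L, seed = 10L)
  fitColor <- fitCp(standardizeTensor(b$colorEmotion), 2, nStarts = 4L,
                    seed = 10L)
  fitMusic <- fitCp(standardizeTensor(b$musicEmotion), 2, nStarts = 4L,
                    seed = 10L)
  expect_true(all(tuckerCongruence(factorMatrix(fitJoint, "scales"),
                                   factorMatrix(fitColor, "scales")) >= 0.95))
  expect_true(all(tuckerCongruence(factorMatrix(fitJoint, "scales"),
                                   factorMatrix(fitMusic, "scales")) >= 0.95))
})

test_that("the nonnegative subject-mode option keeps C nonnegative", {
  set.seed(48)
  A <- matrix(rnorm(16), 8); B <- matrix(rnorm(10), 5)
  C <- matrix(runif(8), 4)  # positive truth
  Z <- trilinearTensor(A, B, C) + array(rnorm(160, sd = 0.05), c(8, 5, 4))
  m <- fitCp(Z, 2, nStarts = 4L, seed = 12L, nonnegC = TRUE)
  expect_true(all(factorMatrix(m, "subjects") >= 0))
  expect_gte(varianceExplained(m), 0.9)
})
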
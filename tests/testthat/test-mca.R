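sixColors <- sprintf("c%d", 1:6)

test_that("identical attribute values score zero (weights sum to zero)", {
  ch <- choiceFixture(sixColors)
  attrs <- matrix(7.3, 6L, 1L, dimnames = list(sixColors, "light/dark"))
  s <- computeMca(ch, attrs)
  expect_equal(unname(scoreValues(s)[1L, 1L]), 0, tolerance = 1e-12)
})

test_that("extreme polarity reaches the attribute bound", {
  ch <- choiceFixture(sixColors)
  attrs <- matrix(c(100, 100, 100, -100, -100, -100), 6L, 1L,
                  dimnames = list(sixColors, "light/dark"))
  s <- computeMca(ch, attrs)
  expect_equal(unname(scoreValues(s)[1L, 1L]), 100)
})

test_that("the weighted aggregation matches hand arithmetic", {
  # best1..3 attrs (10, 20, 30), worst1..3 (40, 0, -10), default weights:
  # (3*10 + 2*20 + 1*30 - 3*40 - 2*0 - 1*(-10)) / 12 = -10/12
  ch <- choiceFixture(sixColors)
  attrs <- matrix(c(10, 20, 30, 40, 0, -10), 6L, 1L,
                  dimnames = list(sixColors, "a"))
  s <- computeMca(ch, attrs)
  expect_equal(unname(scoreValues(s)[1L, 1L]), -10 / 12, tolerance = 1e-12)
})

test_that("factor-weight attributes behave linearly", {
  ch <- choiceFixture(sixColors)
  w0 <- matrix(0, 6L, 2L, dimnames = list(sixColors, c("f1", "f2")))
  expect_true(all(scoreValues(mcaWithFactorAttributes(ch, w0)) == 0))

  w <- matrix(rnorm(6L), 6L, 1L, dimnames = list(sixColors, "f1"))
  dup <- cbind(f1 = w[, 1L], f2 = w[, 1L])
  rownames(dup) <- sixColors
  sd2 <- scoreValues(mcaWithFactorAttributes(ch, dup))
  expect_equal(sd2[, 1L], sd2[, 2L])
})

test_that("a two-color best/worst split of unit factor weights scores 1", {
  # best slots carry factor weight +1, worst slots -1:
  # (3+2+1)*1 + (-3-2-1)*(-1) = 12; /12 = 1
  attrs <- matrix(c(1, 1, 1, -1, -1, -1), 6L, 1L,
                  dimnames = list(sixColors, "f1"))
  s <- mcaWithFactorAttributes(choiceFixture(sixColors), attrs)
  expect_equal(unname(scoreValues(s)[1L, 1L]), 1)
})

test_that("scoring is linear in the attribute table", {
  b <- smallBundle(12L)
  ch <- b$choices
  ids <- b$colors@ids
  set.seed(1)
  X <- matrix(rnorm(length(ids) * 3L), length(ids), 3L,
              dimnames = list(ids, c("a", "b", "c")))
  Y <- matrix(rnorm(length(ids) * 3L), length(ids), 3L,
              dimnames = list(ids, c("a", "b", "c")))
  a <- 1.7; bb <- -0.4
  lhs <- scoreValues(computeMca(ch, a * X + bb * Y))
  rhs <- a * scoreValues(computeMca(ch, X)) +
    bb * scoreValues(computeMca(ch, Y))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("scores are invariant to attribute translation", {
  b <- smallBundle(13L)
  ids <- b$colors@ids
  set.seed(2)
  X <- matrix(rnorm(length(ids) * 2L), length(ids), 2L,
              dimnames = list(ids, c("a", "b")))
  s1 <- scoreValues(computeMca(b$choices, X))
  s2 <- scoreValues(computeMca(b$choices, X + 55.5))
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("swapping best and worst slots negates every score", {
  b <- smallBundle(14L)
  ids <- b$colors@ids
  set.seed(3)
  X <- matrix(rnorm(length(ids) * 2L), length(ids), 2L,
              dimnames = list(ids, c("a", "b")))
  rec <- choiceRecords(b$choices)
  swap <- c(best1 = "worst1", best2 = "worst2", best3 = "worst3",
            worst1 = "best1", worst2 = "best2", worst3 = "best3")
  rec$slot <- unname(swap[rec$slot])
  s1 <- scoreValues(computeMca(b$choices, X))
  s2 <- scoreValues(computeMca(ChoiceTable(rec), X))
  expect_equal(s2, -s1, tolerance = 1e-10)
})

test_that("across-subject scores equal the mean of per-subject scores", {
  b <- smallBundle(15L)
  ids <- b$colors@ids
  set.seed(4)
  X <- matrix(rnorm(length(ids) * 2L), length(ids), 2L,
              dimnames = list(ids, c("a", "b")))
  per <- computeMca(b$choices, X, level = "per_subject")
  expect_equal(apply(perSubjectScores(per), c(1L, 2L), mean),
               scoreValues(per), tolerance = 1e-10)
})

test_that("missing attribute rows and degenerate weights are rejected", {
  ch <- choiceFixture(sixColors)
  attrs <- matrix(1, 5L, 1L, dimnames = list(sixColors[-6L], "a"))
  expect_error(computeMca(ch, attrs), "c6")
  attrs6 <- matrix(1, 6L, 1L, dimnames = list(sixColors, "a"))
  expect_error(computeMca(ch, attrs6, weights = c(best1 = 0, best2 = 0,
                                                  best3 = 0, worst1 = 0,
                                                  worst2 = 0, worst3 = 0)),
               "absolute weights")
})
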
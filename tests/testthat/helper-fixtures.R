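# Small study bundles for fast unit tests; full-size bundles are used only
# where the property under test depends on the study's n.

smallConfig <- function(seed = 1L, mode = "mediated", ...) {
  analysisConfig(synthetic = utils::modifyList(list(
    nColors = 12L, nExcerpts = 16L, nSubjects = 6L, nMusicians = 5L,
    nAppearanceRaters = 6L, seed = as.integer(seed), mode = mode), list(...)),
    parafac = list(nStarts = 4L, maxIter = 200L))
}

smallBundle <- function(seed = 1L, mode = "mediated", ...) {
  generateBundle(smallConfig(seed, mode, ...))
}

# a minimal legal choice table: one subject/excerpt cell per row of `cells`
choiceFixture <- function(colors6, subject = "s1", excerpt = "M01") {
  ChoiceTable(data.frame(
    subject = subject, excerpt = excerpt,
    slot = c("best1", "best2", "best3", "worst1", "worst2", "worst3"),
    color = colors6, stringsAsFactors = FALSE))
}

# noiseless rank-2 tensor from explicit factor matrices
trilinearTensor <- function(A, B, C) {
  d <- c(nrow(A), nrow(B), nrow(C))
  Z <- array(0, d)
  for (r in seq_len(ncol(A)))
    Z <- Z + A[, r] %o% B[, r] %o% C[, r]
  Z
}

# independent CORCONDIA oracle: explicit Kronecker normal-equations core
corcondiaOracle <- function(Z, model) {
  K <- kronecker(factorMatrix(model, "subjects"),
                 kronecker(factorMatrix(model, "scales"),
                           factorMatrix(model, "stimuli")))
  g <- solve(crossprod(K), crossprod(K, as.vector(Z)))
  R <- nFactors(model)
  tgt <- array(0, c(R, R, R))
  for (r in seq_len(R)) tgt[r, r, r] <- 1
  100 * (1 - sum((array(g, c(R, R, R)) - tgt)^2) / R)
}
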
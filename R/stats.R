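#' @include AllClasses.R
NULL

tCdfUpper <- function(t, df) stats::pt(t, df = df, lower.tail = FALSE)

pFromT <- function(t, df, tail) {
  switch(tail,
         two = 2 * tCdfUpper(abs(t), df),
         greater = tCdfUpper(t, df),
         less = stats::pt(t, df = df),
         stop("tail must be 'two', 'greater' or 'less'"))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks are assigned to ties; rho is the Pearson correlation of the
#' ranks, and the p-value uses the t approximation on `n - 2` degrees of
#' freedom, one- or two-tailed. With samples of 30+ stimuli the
#' approximation is standard; it is also the convention used throughout the
#' downstream correlation analyses.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param tail `"two"`, `"greater"` (rho > 0) or `"less"`.
#' @return list with `rho`, `p`, `n`, `df`.
#' @examples
#' spearmanRho(1:5, c(1, 3, 2, 5, 4))$rho  # 0.8
#' @export
spearmanRho <- function(x, y, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho is undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  df <- n - 2L
  if (abs(rho) >= 1) {
    p <- if (tail == "two") 0
         else if (tail == "greater") as.numeric(rho < 0)
         else as.numeric(rho > 0)
  } else {
    t <- rho * sqrt(df / (1 - rho^2))
    p <- pFromT(t, df, tail)
  }
  list(rho = rho, p = p, n = n, df = df)
}

#' Partial Spearman correlation by rank residualization
#'
#' Rank-transforms `x`, `y` and every covariate (mid-ranks), residualizes
#' the ranked `x` and `y` on the ranked covariates by ordinary least squares
#' with intercept, and returns the Pearson correlation of the residuals with
#' a t-approximation p on `n - q - 2` degrees of freedom (q covariates).
#' Residualization (rather than recursive partial-correlation formulas)
#' supports partialling many covariates at once, e.g. all ten emotional MCA
#' scores simultaneously.
#'
#' @param x,y numeric vectors.
#' @param Z numeric matrix of covariates (n x q), or `NULL`/0 columns for a
#'   plain Spearman correlation.
#' @param tail as in [spearmanRho()].
#' @return list with `rho`, `p`, `n`, `df`.
#' @export
partialSpearman <- function(x, y, Z = NULL,
                            tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(Z) || NCOL(Z) == 0L || length(Z) == 0L)
    return(spearmanRho(x, y, tail))
  Z <- as.matrix(Z)
  if (nrow(Z) != n) stop("covariates must have one row per observation")
  q <- ncol(Z)
  if (n <= q + 2L) stop("need n > q + 2 observations for q covariates")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho is undefined for a constant vector")

  rx <- rank(x); ry <- rank(y)
  rz <- apply(Z, 2L, rank)
  design <- cbind(1, rz)
  qrd <- qr(design)
  if (qrd$rank < ncol(design))
    stop("covariates are collinear after ranking")
  ex <- stats::residuals(stats::lm.fit(design, rx))
  ey <- stats::residuals(stats::lm.fit(design, ry))
  if (stats::sd(ex) < 1e-10 * stats::sd(rx) ||
      stats::sd(ey) < 1e-10 * stats::sd(ry))
    stop("a variable is perfectly explained by the covariates")
  rho <- stats::cor(ex, ey)
  df <- n - q - 2L
  if (abs(rho) >= 1) {
    p <- if (tail == "two") 0
         else if (tail == "greater") as.numeric(rho < 0)
         else as.numeric(rho > 0)
  } else {
    t <- rho * sqrt(df / (1 - rho^2))
    p <- pFromT(t, df, tail)
  }
  list(rho = rho, p = p, n = n, df = df)
}

#' Family-wise p-value adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] for the two corrections
#' used here: Holm's step-down method (the default for correlation-matrix
#' families) and Bonferroni (used for the ten matched-scale mediation
#' tests, alpha .05/10).
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param method `"holm"` or `"bonferroni"`.
#' @return adjusted p-values in input order, capped at 1.
#' @export
adjustPvalues <- function(p, method = c("holm", "bonferroni")) {
  method <- match.arg(method)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' All-pairs Spearman correlation matrix as a tidy report
#'
#' Computes every column-pair correlation between two labeled blocks (e.g.
#' the 15 music-perceptual feature averages against the 4 PMCA dimensions)
#' and applies the family-wise correction over the full |X| x |Y| family,
#' matching the convention that each reported figure is one family.
#'
#' @param X,Y numeric matrices with column names and equal row counts
#'   (rows = excerpts).
#' @param Z optional covariate matrix; if given, partial Spearman
#'   correlations are reported and the method is `"partial_spearman"`.
#' @param correction `"holm"`, `"bonferroni"` or `"none"`.
#' @param tail as in [spearmanRho()].
#' @return a [CorrelationReport-class] with |X| * |Y| entries.
#' @export
correlationMatrix <- function(X, Y, Z = NULL,
                              correction = c("holm", "bonferroni", "none"),
                              tail = c("two", "greater", "less")) {
  correction <- match.arg(correction)
  tail <- match.arg(tail)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have equal row counts")
  if (is.null(colnames(X)) || is.null(colnames(Y)))
    stop("X and Y need column names")
  covlab <- if (is.null(Z) || NCOL(Z) == 0L) ""
            else paste(colnames(as.matrix(Z)), collapse = ",")
  grid <- expand.grid(x = colnames(X), y = colnames(Y),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    partialSpearman(X[, grid$x[g]], Y[, grid$y[g]], Z, tail = tail)
  })
  entries <- data.frame(
    x = grid$x, y = grid$y,
    rho = vapply(res, `[[`, 0, "rho"),
    n = vapply(res, `[[`, 0, "n"),
    p = vapply(res, `[[`, 0, "p"),
    tail = tail, covariates = covlab,
    stringsAsFactors = FALSE)
  entries$p_adjusted <- if (correction == "none") entries$p
                        else adjustPvalues(entries$p, correction)
  new("CorrelationReport",
      entries = entries[, c("x", "y", "rho", "n", "p", "p_adjusted",
                            "tail", "covariates")],
      method = if (nzchar(covlab)) "partial_spearman" else "spearman",
      correction = correction)
}

#' Cronbach's alpha for inter-rater consistency
#'
#' \deqn{\alpha = \frac{k}{k-1}\Big(1 - \frac{\sum_j var(rater_j)}
#'   {var(\sum_j rater_j)}\Big)}
#' with sample variances, raters as columns and stimuli as rows.
#'
#' @param ratings stimuli x raters numeric matrix (>= 2 of each).
#' @return alpha (scalar).
#' @export
cronbachAlpha <- function(ratings) {
  ratings <- as.matrix(ratings)
  k <- ncol(ratings)
  if (k < 2L) stop("need at least 2 raters")
  if (nrow(ratings) < 2L) stop("need at least 2 stimuli")
  total <- stats::var(rowSums(ratings))
  if (total <= 0) stop("zero variance of the rater sums")
  k / (k - 1) * (1 - sum(apply(ratings, 2L, stats::var)) / total)
}

#' Hierarchical R-squared with a designated first predictor
#'
#' Ordinary least squares (with intercept) of `response` on two factor-score
#' vectors, entering `first` alone before adding the second predictor;
#' reports the first-model R-squared, the full-model R-squared and the
#' increment. Used to compare how much PMCA variance the two affective
#' factors explain versus the two music-perceptual factors, with factor 1
#' always entered first.
#'
#' @param factors n x 2 numeric matrix with column names (the two factor
#'   scores).
#' @param response numeric vector of length n.
#' @param first column name of the predictor entered first (default the
#'   first column).
#' @param responseLabel label stored in the result.
#' @return a [VariancePartition-class].
#' @export
hierarchicalR2 <- function(factors, response, first = colnames(factors)[1L],
                           responseLabel = "response") {
  factors <- as.matrix(factors)
  if (ncol(factors) != 2L) stop("exactly two predictors are expected")
  if (is.null(colnames(factors))) stop("factors needs column names")
  if (!first %in% colnames(factors)) stop("unknown first predictor: ", first)
  n <- length(response)
  if (nrow(factors) != n) stop("row mismatch")
  if (n <= 3L) stop("need more than 3 observations")
  if (qr(cbind(1, factors))$rank < 3L) stop("collinear predictors")

  second <- setdiff(colnames(factors), first)
  f1 <- factors[, first]; f2 <- factors[, second]
  m1 <- stats::lm(response ~ f1)
  m2 <- stats::lm(response ~ f1 + f2)
  tss <- sum((response - mean(response))^2)
  if (tss <= 0) stop("constant response")
  r2First <- 1 - sum(stats::residuals(m1)^2) / tss
  r2Total <- 1 - sum(stats::residuals(m2)^2) / tss
  co <- stats::coef(m2)[-1L]
  signs <- sign(co)
  names(signs) <- c(first, second)
  new("VariancePartition", response = responseLabel, firstEntered = first,
      r2First = r2First, r2Total = max(r2Total, r2First),
      r2Increment = max(r2Total, r2First) - r2First, signs = signs)
}
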
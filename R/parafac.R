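#' @include AllClasses.R config.R
NULL

# mode-n unfoldings (column-major; mode index runs fastest down each column)
unfold1 <- function(Z) { d <- dim(Z); dim(Z) <- c(d[1L], d[2L] * d[3L]); Z }
unfold2 <- function(Z) { d <- dim(Z); Z <- aperm(Z, c(2L, 1L, 3L))
  dim(Z) <- c(d[2L], d[1L] * d[3L]); Z }
unfold3 <- function(Z) { d <- dim(Z); Z <- aperm(Z, c(3L, 1L, 2L))
  dim(Z) <- c(d[3L], d[1L] * d[2L]); Z }

# columnwise Khatri-Rao product with Y's row index running fastest,
# so kr(C, B) matches the column order of unfold1 (j fastest, then k)
kr <- function(X, Y) {
  X[rep(seq_len(nrow(X)), each = nrow(Y)), , drop = FALSE] *
    Y[rep(seq_len(nrow(Y)), times = nrow(X)), , drop = FALSE]
}

# multiply array Z along `mode` by matrix M (rows of the result = rows of M)
modeProduct <- function(Z, M, mode) {
  d <- dim(Z)
  out <- switch(mode,
    `1` = M %*% unfold1(Z),
    `2` = M %*% unfold2(Z),
    `3` = M %*% unfold3(Z))
  dn <- d; dn[mode] <- nrow(M)
  out <- switch(mode,
    `1` = array(out, dim = dn),
    `2` = aperm(array(out, dim = c(dn[2L], dn[1L], dn[3L])), c(2L, 1L, 3L)),
    `3` = aperm(array(out, dim = c(dn[3L], dn[1L], dn[2L])), c(2L, 3L, 1L)))
  out
}

permutationsOf <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutationsOf(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

asTensorArray <- function(tensor, allowRaw = FALSE) {
  if (is(tensor, "RatingsTensor")) {
    if (!tensor@standardized && !allowRaw)
      stop("tensor is not standardized; standardizeTensor() it first or ",
           "pass allowRaw = TRUE to fit the raw ratings")
    tensor@values
  } else if (is.array(tensor) && length(dim(tensor)) == 3L) {
    tensor
  } else stop("expected a RatingsTensor or a 3-d array")
}

#' Standardize a ratings tensor
#'
#' Default scheme: center and scale each (scale, subject) fiber across
#' stimuli to mean 0, SD 1 (sample SD). This removes per-subject,
#' per-scale response-style differences (offset and spread of scale usage)
#' so the trilinear factors capture the shared stimulus structure.
#' Alternatives: `"scale"` centers/scales each rating scale globally across
#' stimuli and subjects; `"none"` leaves values untouched and only flags the
#' tensor as ready for fitting.
#'
#' @param raw an unstandardized [RatingsTensor-class].
#' @param scheme `"fiber"` (default), `"scale"`, or `"none"`.
#' @param sdType `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a standardized [RatingsTensor-class].
#' @export
standardizeTensor <- function(raw, scheme = c("fiber", "scale", "none"),
                              sdType = c("sample", "population")) {
  scheme <- match.arg(scheme)
  sdType <- match.arg(sdType)
  if (!is(raw, "RatingsTensor")) stop("expected a RatingsTensor")
  if (raw@standardized) stop("tensor is already standardized")
  Z <- raw@values
  d <- dim(Z)
  denom <- function(n) if (sdType == "sample") n - 1L else n

  if (scheme == "fiber") {
    m <- colMeans(Z)                        # scales x subjects
    ctr <- sweep(Z, c(2L, 3L), m)
    s <- sqrt(apply(ctr^2, c(2L, 3L), sum) / denom(d[1L]))
    if (any(s <= 0)) {
      w <- which(s <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("zero-variance fiber at (scale %s, subject %s)",
                   raw@scales$name[w[1L]], raw@subjects[w[2L]]))
    }
    Z <- sweep(ctr, c(2L, 3L), s, "/")
  } else if (scheme == "scale") {
    for (j in seq_len(d[2L])) {
      v <- Z[, j, ]
      s <- sqrt(sum((v - mean(v))^2) / denom(length(v)))
      if (s <= 0)
        stop(sprintf("zero-variance scale %s", raw@scales$name[j]))
      Z[, j, ] <- (v - mean(v)) / s
    }
  }
  RatingsTensor(Z, raw@stimuli, raw@scales, raw@subjects, standardized = TRUE)
}

#' Fit a Parafac (CP) model by multi-start alternating least squares
#'
#' Fits the trilinear model \eqn{z_{ijk} \approx \sum_r a_{ir} b_{jr}
#' c_{kr}} to a stimuli x scales x subjects tensor. Each random start
#' initializes the scale (B) and subject (C) factors uniform(-1, 1) and
#' iterates exact least-squares updates of the three modes until the
#' relative SSE decrease (relative to the tensor's total sum of squares)
#' falls below `tol` or `maxIter` is reached; the best-SSE start is
#' retained. Within a start the SSE is non-increasing by construction (each
#' mode update is an exact least-squares solve); the per-iteration trace is
#' kept on the model. On return, columns of B and C are unit-norm with all
#' scale absorbed into A, factors are ordered by decreasing stimulus-weight
#' mass, and signs are fixed deterministically (largest-magnitude B and C
#' loadings positive). Use [alignFactors()] for a substantive orientation.
#'
#' @param tensor a standardized [RatingsTensor-class] (or a raw one with
#'   `allowRaw = TRUE`), or a plain 3-d array.
#' @param R number of factors (>= 1, at most the smallest mode length).
#' @param nStarts number of random starts (default 10).
#' @param tol relative SSE-change convergence threshold (default 1e-8).
#' @param maxIter maximum ALS iterations per start (default 500).
#' @param seed integer; start s uses seed `seed + s - 1`, so the fit is
#'   deterministic.
#' @param nonnegC if `TRUE`, the subject mode is constrained nonnegative by
#'   a projected update (negative entries clamped to zero after the
#'   least-squares solve).
#' @param allowRaw permit fitting an unstandardized RatingsTensor.
#' @return a [CpModel-class].
#' @references Harshman's PARAFAC; see also Bro's multiway analysis
#'   tutorial literature.
#' @export
fitCp <- function(tensor, R, nStarts = 10L, tol = 1e-8, maxIter = 500L,
                  seed = 1L, nonnegC = FALSE, allowRaw = FALSE) {
  Z <- asTensorArray(tensor, allowRaw)
  if (!all(is.finite(Z))) stop("tensor contains non-finite values")
  d <- dim(Z)
  R <- as.integer(R)
  if (R < 1L) stop("R must be >= 1")
  if (R > min(d)) stop("R exceeds a mode length (", paste(d, collapse = "x"),
                       ")")
  Z1 <- unfold1(Z); Z2 <- unfold2(Z); Z3 <- unfold3(Z)
  totalSS <- sum(Z^2)
  if (totalSS == 0) stop("tensor is identically zero")

  solveMode <- function(Zn, U, V) {
    # LS update of one mode: Zn ~ X (U kr V)^T; a vanishing ridge guards
    # against transiently degenerate factors (e.g. under the nonnegative
    # projection) without measurably perturbing the solve otherwise
    G <- crossprod(U) * crossprod(V)
    if (rcond(G) < 1e-12)
      G <- G + diag(1e-9 * mean(diag(G)) + 1e-300, ncol(G))
    t(solve(G, t(Zn %*% kr(U, V))))
  }

  best <- NULL
  for (s in seq_len(nStarts)) {
    startSeed <- as.integer(seed + s - 1L)
    B <- withSeed(startSeed, matrix(stats::runif(d[2L] * R, -1, 1), d[2L], R))
    C <- withSeed(startSeed + 104729L,
                  matrix(stats::runif(d[3L] * R, -1, 1), d[3L], R))
    A <- matrix(0, d[1L], R)
    ssePrev <- Inf
    trace <- numeric(0)
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
      it <- it + 1L
      A <- solveMode(Z1, C, B)
      B <- solveMode(Z2, C, A)
      C <- solveMode(Z3, B, A)
      if (nonnegC) {
        # resolve the sign indeterminacy toward the nonnegative orthant
        # first (flipping C and A jointly leaves the model unchanged),
        # then project
        for (r in seq_len(R)) {
          if (sum(C[, r]) < 0) {
            C[, r] <- -C[, r]; A[, r] <- -A[, r]
          }
        }
        C <- pmax(C, 0)
        zero <- colSums(C) == 0
        if (any(zero)) C[, zero] <- 1e-8
      }
      sse <- sum((Z1 - A %*% t(kr(C, B)))^2)
      trace <- c(trace, sse)
      if (is.finite(ssePrev) && (ssePrev - sse) / totalSS < tol) {
        converged <- TRUE
        break
      }
      ssePrev <- sse
    }
    sse <- trace[length(trace)]
    if (is.null(best) || sse < best$sse) {
      best <- list(A = A, B = B, C = C, sse = sse, trace = trace,
                   nIter = it, converged = converged, startSeed = startSeed)
    }
  }

  A <- best$A; B <- best$B; C <- best$C
  # normalization convention: unit-norm B and C columns, scale into A
  for (r in seq_len(R)) {
    nb <- sqrt(sum(B[, r]^2)); nc <- sqrt(sum(C[, r]^2))
    if (nb == 0 || nc == 0) stop("degenerate zero factor in solution")
    B[, r] <- B[, r] / nb; C[, r] <- C[, r] / nc
    A[, r] <- A[, r] * nb * nc
  }
  ord <- order(colSums(A^2), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]
  for (r in seq_len(R)) {
    if (B[which.max(abs(B[, r])), r] < 0) {
      B[, r] <- -B[, r]; A[, r] <- -A[, r]
    }
    if (C[which.max(abs(C[, r])), r] < 0) {
      C[, r] <- -C[, r]; A[, r] <- -A[, r]
    }
  }
  if (is(tensor, "RatingsTensor")) {
    rownames(A) <- tensor@stimuli@ids
    rownames(B) <- tensor@scales$name
    rownames(C) <- tensor@subjects
  } else {
    rownames(A) <- dimnames(Z)[[1L]]
    rownames(B) <- dimnames(Z)[[2L]]
    rownames(C) <- dimnames(Z)[[3L]]
  }
  colnames(A) <- colnames(B) <- colnames(C) <- paste0("factor", seq_len(R))
  # exact-match Class=: a slot named "C" would otherwise partial-match it
  new(Class = "CpModel", A = A, B = B, C = C, R = R, sse = best$sse,
      totalSS = totalSS, varianceExplained = max(0, 1 - best$sse / totalSS),
      nIter = best$nIter, converged = best$converged,
      startSeed = best$startSeed, sseTrace = best$trace)
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Solves the least-squares Tucker core G of the tensor given the fitted CP
#' factor matrices and compares it to the superdiagonal target T (ones on
#' the superdiagonal, zero elsewhere — the core a perfect CP structure
#' implies):
#' \deqn{100 \Big(1 - \frac{\sum (g - t)^2}{\sum t^2}\Big)}
#' Values near 100 support the CP structure at this rank; values far below
#' (possibly negative) indicate over-factoring.
#'
#' @param tensor the tensor the model was fitted on (RatingsTensor or array).
#' @param model the fitted [CpModel-class].
#' @return the diagnostic in percent (scalar, may be negative).
#' @export
corcondia <- function(tensor, model) {
  Z <- asTensorArray(tensor, allowRaw = TRUE)
  if (!identical(dim(Z), c(nrow(model@A), nrow(model@B), nrow(model@C))))
    stop("model was not fitted on a tensor of these dimensions")
  pinv <- function(X) {
    G <- crossprod(X)
    if (rcond(G) < 1e-12) stop("singular factor cross-product")
    solve(G, t(X))
  }
  core <- modeProduct(modeProduct(modeProduct(Z, pinv(model@A), 1L),
                                  pinv(model@B), 2L), pinv(model@C), 3L)
  R <- model@R
  target <- array(0, dim = c(R, R, R))
  for (r in seq_len(R)) target[r, r, r] <- 1
  100 * (1 - sum((core - target)^2) / R)
}

#' Scree table over a range of factor counts
#'
#' Fits the CP model for each R in `Rrange` (each with the full multi-start
#' protocol) and tabulates fit and core consistency, supporting
#' model-selection by scree shape and CORCONDIA drop.
#'
#' @inheritParams fitCp
#' @param Rrange integer vector of factor counts (default 2:10, truncated
#'   to the mode bounds by the caller).
#' @return data.frame with columns `R`, `sse`, `varianceExplained`,
#'   `corcondia`, `converged`.
#' @export
screeCp <- function(tensor, Rrange = 2:10, nStarts = 10L, tol = 1e-8,
                    maxIter = 500L, seed = 1L, nonnegC = FALSE,
                    allowRaw = FALSE) {
  Rrange <- as.integer(Rrange)
  if (length(Rrange) == 0L)
    return(data.frame(R = integer(), sse = numeric(),
                      varianceExplained = numeric(), corcondia = numeric(),
                      converged = logical()))
  rows <- lapply(Rrange, function(R) {
    m <- fitCp(tensor, R, nStarts = nStarts, tol = tol, maxIter = maxIter,
               seed = seed, nonnegC = nonnegC, allowRaw = allowRaw)
    data.frame(R = R, sse = m@sse, varianceExplained = m@varianceExplained,
               corcondia = corcondia(tensor, m), converged = m@converged)
  })
  do.call(rbind, rows)
}

#' Resolve CP sign/permutation indeterminacy against anchor scales
#'
#' A CP solution is unique only up to factor order and paired sign flips.
#' This orients a fitted model substantively: `anchors` maps scale names to
#' factor indices (e.g. the agitated/calm scale to factor 1 = arousal, the
#' happy/sad scale to factor 2 = valence); columns are permuted so each
#' anchored scale loads most strongly on its assigned factor, then signs are
#' flipped (jointly in A and B, leaving every reconstructed value and the
#' SSE unchanged) so the anchored loadings are positive.
#'
#' @param model a fitted [CpModel-class] with scale rownames on B.
#' @param anchors named integer vector: `c("agitated/calm" = 1,
#'   "happy/sad" = 2)`.
#' @return the aligned [CpModel-class]; identical fit statistics.
#' @export
alignFactors <- function(model, anchors) {
  if (is.null(names(anchors)) || any(!nzchar(names(anchors))))
    stop("anchors must be a named vector (scale name -> factor index)")
  if (anyDuplicated(names(anchors)))
    stop("contradictory anchor: a scale is anchored to two factors")
  B <- model@B
  missing <- setdiff(names(anchors), rownames(B))
  if (length(missing))
    stop("anchor scale(s) not in the model: ", paste(missing, collapse = ", "))
  R <- model@R
  if (any(anchors < 1L | anchors > R)) stop("anchor factor index out of range")
  if (R > 8L) stop("alignment by exhaustive permutation supports R <= 8")

  rowIdx <- match(names(anchors), rownames(B))
  perms <- permutationsOf(R)
  score <- apply(perms, 1L, function(p) {
    sum(abs(B[cbind(rowIdx, p[anchors])]))
  })
  p <- perms[which.max(score), ]
  # column p[f] of the fit becomes factor f
  A <- model@A[, p, drop = FALSE]
  B <- B[, p, drop = FALSE]
  C <- model@C[, p, drop = FALSE]
  for (f in unique(unname(anchors))) {
    sc <- names(anchors)[anchors == f]
    if (sum(B[sc, f]) < 0) {
      B[, f] <- -B[, f]; A[, f] <- -A[, f]
    }
  }
  colnames(A) <- colnames(B) <- colnames(C) <- paste0("factor", seq_len(R))
  methods::initialize(model, A = A, B = B, C = C)
}

#' Tucker congruence between two factor matrices
#'
#' Per-factor cosine similarity after the optimal column matching:
#' columns are normalized, matched by exhaustive permutation search
#' (maximizing total absolute congruence), and signs are resolved by taking
#' absolute values — CP factors are only identified up to paired sign
#' flips. Used to quantify recovery of planted factors.
#'
#' @param M1,M2 numeric matrices with equal row counts and the same number
#'   of columns (R <= 8).
#' @return numeric vector of per-factor congruences (order of `M1`'s
#'   columns), with the matched permutation as attribute `"perm"`.
#' @export
tuckerCongruence <- function(M1, M2) {
  M1 <- as.matrix(M1); M2 <- as.matrix(M2)
  if (nrow(M1) != nrow(M2)) stop("row counts differ")
  if (ncol(M1) != ncol(M2)) stop("column counts differ")
  R <- ncol(M1)
  if (R > 8L) stop("exhaustive matching supports R <= 8")
  n1 <- sqrt(colSums(M1^2)); n2 <- sqrt(colSums(M2^2))
  if (any(n1 == 0) || any(n2 == 0)) stop("zero-norm factor column")
  G <- abs(crossprod(sweep(M1, 2L, n1, "/"), sweep(M2, 2L, n2, "/")))
  perms <- permutationsOf(R)
  tot <- apply(perms, 1L, function(p) sum(G[cbind(seq_len(R), p)]))
  p <- perms[which.max(tot), ]
  phi <- G[cbind(seq_len(R), p)]
  names(phi) <- colnames(M1)
  attr(phi, "perm") <- p
  phi
}

#' Stack color- and music-emotion tensors into the joint tensor
#'
#' Both modalities were rated by the same subjects on the same bipolar
#' emotion scales, so the stimulus axes concatenate cleanly: colors first,
#' then musical excerpts. The joint fit then extracts affect factors shared
#' across modalities. Optionally each modality block is rescaled to equal
#' total sum of squares first, so neither modality dominates the fit by
#' sheer variance.
#'
#' @param colorEmotion,musicEmotion [RatingsTensor-class] objects sharing
#'   scales and subjects (both standardized or both raw).
#' @param equalizeModalityVariance rescale each block to equal total SS.
#' @return list with `tensor` (the joint [RatingsTensor-class]) and `index`
#'   (a [JointStimulusIndex-class]).
#' @export
jointEmotionTensor <- function(colorEmotion, musicEmotion,
                               equalizeModalityVariance = FALSE) {
  if (!identical(scaleNames(colorEmotion), scaleNames(musicEmotion)))
    stop("scale sets differ between modalities")
  if (!identical(subjectIds(colorEmotion), subjectIds(musicEmotion)))
    stop("subject sets differ between modalities")
  if (colorEmotion@standardized != musicEmotion@standardized)
    stop("mixed standardization between modalities")
  Zc <- colorEmotion@values
  Zm <- musicEmotion@values
  if (equalizeModalityVariance) {
    Zc <- Zc / sqrt(sum(Zc^2))
    Zm <- Zm / sqrt(sum(Zm^2))
  }
  d <- dim(Zc)
  joint <- array(0, dim = c(d[1L] + dim(Zm)[1L], d[2L], d[3L]))
  joint[seq_len(d[1L]), , ] <- Zc
  joint[d[1L] + seq_len(dim(Zm)[1L]), , ] <- Zm
  ids <- c(colorEmotion@stimuli@ids, musicEmotion@stimuli@ids)
  meta <- data.frame(modality = rep(c("color", "music"),
                                    c(d[1L], dim(Zm)[1L])),
                     stringsAsFactors = FALSE)
  stim <- StimulusSet(ids, "joint", meta)
  tensor <- RatingsTensor(joint, stim, colorEmotion@scales,
                          colorEmotion@subjects,
                          standardized = colorEmotion@standardized)
  list(tensor = tensor, index = JointStimulusIndex(d[1L], dim(Zm)[1L]))
}

#' Split joint stimulus weights into color and music blocks
#'
#' @param model a [CpModel-class] fitted on the joint tensor.
#' @param index the [JointStimulusIndex-class] from [jointEmotionTensor()].
#' @return list with matrices `color` and `music` (views of A's rows; their
#'   vertical restacking reproduces A exactly).
#' @export
splitJointScores <- function(model, index) {
  n <- nrow(model@A)
  if (length(index@colorRows) + length(index@musicRows) != n)
    stop("index does not partition the stimulus mode (", n, " rows)")
  list(color = model@A[index@colorRows, , drop = FALSE],
       music = model@A[index@musicRows, , drop = FALSE])
}
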
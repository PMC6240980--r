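#' @include AllClasses.R config.R data_io.R mca.R stats.R parafac.R
NULL

#' Across-subject mean table of a ratings tensor
#'
#' @param tensor a [RatingsTensor-class].
#' @return stimuli x scales matrix of plain means over the subject mode.
#' @export
acrossSubjectMeans <- function(tensor) {
  apply(tensor@values, c(1L, 2L), mean)
}

#' Perceptual MCA scores of a bundle
#'
#' Weighted best/worst aggregation of the across-subject average
#' color-appearance ratings over the chosen colors: one row per excerpt,
#' one column per appearance dimension.
#'
#' @param bundle a study bundle (see [generateBundle()]).
#' @param weights slot weights, see [computeMca()].
#' @return excerpts x 4 matrix (PMCAs), rows ordered as the excerpt set.
#' @export
computePmca <- function(bundle, weights = bundle$config$mcaWeights) {
  attrs <- acrossSubjectMeans(bundle$colorAppearance)
  s <- computeMca(bundle$choices, attrs, weights = weights)
  s@values[bundle$excerpts@ids, , drop = FALSE]
}

#' Emotional MCA scores of a bundle
#'
#' Same aggregation with the across-subject average color-emotion ratings
#' as attributes: one row per excerpt, one column per emotion scale.
#'
#' @inheritParams computePmca
#' @return excerpts x scales matrix (EMCAs).
#' @export
computeEmca <- function(bundle, weights = bundle$config$mcaWeights) {
  attrs <- acrossSubjectMeans(bundle$colorEmotion)
  s <- computeMca(bundle$choices, attrs, weights = weights)
  s@values[bundle$excerpts@ids, , drop = FALSE]
}

#' Music-perceptual features vs. PMCA correlations
#'
#' The lower-level analysis: all Spearman correlations between the
#' across-musician average music-perceptual features and the four PMCA
#' dimensions (a 15 x 4 = 60-test family under Holm correction by default).
#' A PMCA matrix may be supplied directly — e.g. ingested from a printed
#' table — instead of being recomputed from choices.
#'
#' @param bundle a study bundle.
#' @param pmca optional excerpts x 4 PMCA matrix (rownames = excerpt ids);
#'   computed from the bundle when `NULL`.
#' @param correction family-wise correction over the full matrix.
#' @return a [CorrelationReport-class].
#' @export
runFeaturePmcaAnalysis <- function(bundle, pmca = NULL,
                                   correction = bundle$config$correction) {
  feats <- acrossSubjectMeans(bundle$musicFeatures)
  if (is.null(pmca)) pmca <- computePmca(bundle)
  pmca <- alignRows(pmca, rownames(feats), "PMCA table")
  correlationMatrix(feats, pmca, correction = correction, tail = "two")
}

#' Music-emotion ratings vs. PMCA correlations
#'
#' The higher-level analysis: across-subject average music-emotion ratings
#' against the four PMCA dimensions (10 x 4 family).
#'
#' @inheritParams runFeaturePmcaAnalysis
#' @return a [CorrelationReport-class].
#' @export
runEmotionPmcaAnalysis <- function(bundle, pmca = NULL,
                                   correction = bundle$config$correction) {
  emo <- acrossSubjectMeans(bundle$musicEmotion)
  if (is.null(pmca)) pmca <- computePmca(bundle)
  pmca <- alignRows(pmca, rownames(emo), "PMCA table")
  correlationMatrix(emo, pmca, correction = correction, tail = "two")
}

# keep a maximal set of covariate columns whose rank transforms are
# linearly independent (with intercept); partialling is invariant to
# dropping the redundant ones
dropRankCollinear <- function(Z) {
  rz <- apply(Z, 2L, rank)
  q <- qr(cbind(1, rz))
  keep <- sort(setdiff(q$pivot[seq_len(q$rank)], 1L) - 1L)
  Z[, keep, drop = FALSE]
}

alignRows <- function(m, ids, what) {
  if (is.null(rownames(m))) {
    if (nrow(m) != length(ids))
      stop(what, " has no rownames and a mismatched row count")
    rownames(m) <- ids
    return(m)
  }
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stop(what, " misses excerpt(s): ", paste(missing, collapse = ", "))
  m[ids, , drop = FALSE]
}

#' Matched-scale EMCA mediation tests
#'
#' For every emotion scale s, correlates the across-subject average
#' music-emotion rating on s with the EMCA score on the same scale — the
#' direct test of whether people chose colors whose emotional associations
#' matched the music's. One-tailed (positive) by convention, Bonferroni
#' over the 10 matched tests (alpha .05/10).
#'
#' @param bundle a study bundle.
#' @param weights MCA slot weights.
#' @param tail test tail (default `"greater"`).
#' @return a [CorrelationReport-class] with one entry per scale.
#' @export
runEmcaMediation <- function(bundle, weights = bundle$config$mcaWeights,
                             tail = bundle$config$emcaTail) {
  emo <- acrossSubjectMeans(bundle$musicEmotion)
  emca <- computeEmca(bundle, weights)
  mismatch <- setdiff(colnames(emo), colnames(emca))
  if (length(mismatch))
    stop("scale(s) missing from the color-emotion table: ",
         paste(mismatch, collapse = ", "))
  emca <- emca[rownames(emo), colnames(emo), drop = FALSE]
  res <- lapply(colnames(emo), function(s)
    spearmanRho(emo[, s], emca[, s], tail = tail))
  entries <- data.frame(
    x = colnames(emo), y = paste0("EMCA:", colnames(emo)),
    rho = vapply(res, `[[`, 0, "rho"),
    n = vapply(res, `[[`, 0, "n"),
    p = vapply(res, `[[`, 0, "p"),
    tail = tail, covariates = "", stringsAsFactors = FALSE)
  entries$p_adjusted <- adjustPvalues(entries$p, "bonferroni")
  new("CorrelationReport",
      entries = entries[, c("x", "y", "rho", "n", "p", "p_adjusted", "tail",
                            "covariates")],
      method = "spearman", correction = "bonferroni")
}

#' Feature-PMCA correlations before and after partialling out affect
#'
#' The mediation contrast: the full feature x PMCA matrix is computed
#' twice, without covariates and with the emotional associations partialled
#' out — either the ten EMCA scales or the two latent music-stimulus affect
#' factor scores from the joint Parafac fit. Under pure emotional
#' mediation the significant correlations of the first matrix are
#' eliminated in the second; under a direct music-to-color channel some
#' survive.
#'
#' @param bundle a study bundle.
#' @param covariateSource `"emca_scales"` (10 EMCAs) or `"factor_scores"`
#'   (2 joint-Parafac music affect scores).
#' @param musicFactorScores optional excerpts x 2 matrix; when `NULL` and
#'   `covariateSource = "factor_scores"`, the joint Parafac fit is computed
#'   from the bundle with the config's Parafac options.
#' @param pmca optional PMCA matrix (see [runFeaturePmcaAnalysis()]).
#' @param alpha significance level on adjusted p-values for the counts.
#' @return list: `before` and `after` ([CorrelationReport-class]),
#'   `nSigBefore`, `nSigAfter`.
#' @export
runPartialling <- function(bundle,
                           covariateSource = c("emca_scales",
                                               "factor_scores"),
                           musicFactorScores = NULL, pmca = NULL,
                           alpha = 0.05) {
  covariateSource <- match.arg(covariateSource)
  feats <- acrossSubjectMeans(bundle$musicFeatures)
  if (is.null(pmca)) pmca <- computePmca(bundle)
  pmca <- alignRows(pmca, rownames(feats), "PMCA table")
  Z <- if (covariateSource == "emca_scales") {
    emca <- computeEmca(bundle)
    colnames(emca) <- paste0("EMCA:", colnames(emca))
    # redundant covariates (identical rank orderings do occur between
    # near-synonymous scales) span no extra space; keep an independent set
    dropRankCollinear(emca)
  } else {
    if (is.null(musicFactorScores)) {
      fit <- jointAffectFit(bundle)
      musicFactorScores <- fit$musicScores
    }
    alignRows(musicFactorScores, rownames(feats), "factor scores")
  }
  before <- correlationMatrix(feats, pmca,
                              correction = bundle$config$correction,
                              tail = "two")
  after <- correlationMatrix(feats, pmca, Z = Z,
                             correction = bundle$config$correction,
                             tail = "two")
  list(before = before, after = after,
       nSigBefore = nrow(significantEntries(before, alpha)),
       nSigAfter = nrow(significantEntries(after, alpha)))
}

#' Joint two-factor affect fit of a bundle
#'
#' Stacks the color- and music-emotion tensors, standardizes per
#' (scale, subject) fiber, fits the Parafac model at the configured rank
#' (default 2), aligns factor 1 to the agitated/calm pole and factor 2 to
#' the happy/sad pole when those scales are present, and splits the
#' stimulus weights into color and music blocks.
#'
#' @param bundle a study bundle.
#' @param anchors scale-to-factor orientation map for [alignFactors()];
#'   `NULL` skips alignment.
#' @return list: `model` ([CpModel-class]), `index`, `colorScores`
#'   (colors x R), `musicScores` (excerpts x R), `tensor` (the standardized
#'   joint [RatingsTensor-class]).
#' @export
jointAffectFit <- function(bundle, anchors = NULL) {
  joint <- jointEmotionTensor(bundle$colorEmotion, bundle$musicEmotion)
  std <- standardizeTensor(joint$tensor)
  pf <- bundle$config$parafac
  model <- fitCp(std, R = pf$nFactors, nStarts = pf$nStarts, tol = pf$tol,
                 maxIter = pf$maxIter, seed = pf$seed,
                 nonnegC = isTRUE(pf$nonnegC))
  if (is.null(anchors)) {
    cand <- c("agitated/calm" = 1L, "happy/sad" = 2L)
    cand <- cand[names(cand) %in% rownames(model@B)]
    if (length(cand) == min(2L, pf$nFactors) && pf$nFactors >= 2L)
      anchors <- cand
  }
  if (!is.null(anchors)) model <- alignFactors(model, anchors)
  blocks <- splitJointScores(model, joint$index)
  nm <- paste0("factor", seq_len(ncol(blocks$color)))
  if (length(nm) >= 2L) nm[1:2] <- c("arousal", "valence")
  colnames(blocks$color) <- colnames(blocks$music) <- nm
  list(model = model, index = joint$index, colorScores = blocks$color,
       musicScores = blocks$music, tensor = std)
}

#' Music-perceptual two-factor fit of a bundle
#'
#' Standardizes the musician ratings tensor and fits a two-factor Parafac
#' model, giving the electronic/acoustic- and fast/slow-style perceptual
#' factor scores of the excerpts.
#'
#' @param bundle a study bundle.
#' @return list: `model` and `scores` (excerpts x R stimulus weights).
#' @export
perceptualFactorFit <- function(bundle) {
  std <- standardizeTensor(bundle$musicFeatures)
  pf <- bundle$config$parafac
  model <- fitCp(std, R = pf$nFactors, nStarts = pf$nStarts, tol = pf$tol,
                 maxIter = pf$maxIter, seed = pf$seed,
                 nonnegC = isTRUE(pf$nonnegC))
  scores <- model@A
  colnames(scores) <- paste0("perceptual", seq_len(ncol(scores)))
  list(model = model, scores = scores)
}

#' MLR comparison of affective vs. perceptual factor predictions
#'
#' For each of the four PMCA dimensions, fits ordinary least squares on the
#' two affective factor scores (arousal, valence) and, separately, on the
#' two music-perceptual factor scores — factor 1 always entered first —
#' and partitions the explained variance. Reports the across-dimension
#' mean total R-squared per factor pair.
#'
#' @param bundle a study bundle.
#' @param affectScores excerpts x 2 affective factor scores (from
#'   [jointAffectFit()]; computed when `NULL`).
#' @param perceptualScores excerpts x 2 perceptual factor scores (from
#'   [perceptualFactorFit()]; computed when `NULL`).
#' @param pmca optional PMCA matrix.
#' @return list: `partitions` (data.frame, one row per response x pair) and
#'   `summary` (mean total R-squared per pair).
#' @export
runMlrComparison <- function(bundle, affectScores = NULL,
                             perceptualScores = NULL, pmca = NULL) {
  if (is.null(pmca)) pmca <- computePmca(bundle)
  if (is.null(affectScores)) affectScores <- jointAffectFit(bundle)$musicScores
  if (is.null(perceptualScores))
    perceptualScores <- perceptualFactorFit(bundle)$scores
  affectScores <- alignRows(affectScores, rownames(pmca), "affect scores")
  perceptualScores <- alignRows(perceptualScores, rownames(pmca),
                                "perceptual scores")
  pairs <- list(affective = affectScores, perceptual = perceptualScores)
  rows <- list()
  for (pair in names(pairs)) {
    scores <- pairs[[pair]]
    for (d in colnames(pmca)) {
      vp <- hierarchicalR2(scores, pmca[, d],
                           first = colnames(scores)[1L], responseLabel = d)
      rows[[length(rows) + 1L]] <- data.frame(
        response = d, pair = pair, firstEntered = vp@firstEntered,
        r2First = vp@r2First, r2Total = vp@r2Total,
        r2Increment = vp@r2Increment,
        signFirst = unname(vp@signs[1L]), signSecond = unname(vp@signs[2L]),
        stringsAsFactors = FALSE)
    }
  }
  partitions <- do.call(rbind, rows)
  summary <- stats::aggregate(r2Total ~ pair, data = partitions, FUN = mean)
  colnames(summary) <- c("pair", "meanR2Total")
  list(partitions = partitions, summary = summary)
}

#' Per-scale inter-rater reliability of a bundle
#'
#' Cronbach's alpha of every rating scale in each tensor, raters as
#' columns and stimuli as rows.
#'
#' @param bundle a study bundle.
#' @return data.frame with columns `table`, `scale`, `alpha`, `nRaters`.
#' @export
runReliability <- function(bundle) {
  tables <- c("colorEmotion", "musicEmotion", "musicFeatures",
              "colorAppearance")
  rows <- lapply(tables, function(tb) {
    tensor <- bundle[[tb]]
    data.frame(
      table = tb, scale = scaleNames(tensor),
      alpha = vapply(seq_along(scaleNames(tensor)), function(j)
        cronbachAlpha(tensor@values[, j, ]), 0),
      nRaters = length(subjectIds(tensor)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

writeReport <- function(report, path) {
  utils::write.csv(reportEntries(report), path, row.names = FALSE)
  invisible(path)
}

#' Run the complete analysis pipeline
#'
#' Executes every stage on one bundle — validation, reliability, PMCA/EMCA
#' scoring, the joint and music-perceptual Parafac fits (with scree and
#' core consistency over 2..min(10, bounds) factors), the three
#' correlation-matrix analyses, the matched-scale EMCA mediation tests and
#' their Parafac-based counterpart, both partialling analyses, and the MLR
#' comparison — writing every table as CSV under `outDir` plus a
#' machine-readable manifest with md5 hashes. Reruns with the same config
#' produce identical numeric artifacts.
#'
#' @param config an [analysisConfig()].
#' @param outDir output directory (created if needed).
#' @param bundle optional pre-built bundle; when `NULL`, a synthetic bundle
#'   is generated from the config (`simulate` must be `TRUE`).
#' @param simulate whether generating a synthetic bundle is permitted.
#' @param scree whether to emit the scree/CORCONDIA table (the costly
#'   model-selection sweep); the pipeline itself proceeds at the configured
#'   rank regardless.
#' @return the manifest, invisibly (named list; also written as
#'   `manifest.json`).
#' @export
runAll <- function(config = analysisConfig(), outDir, bundle = NULL,
                   simulate = is.null(bundle), scree = TRUE) {
  if (is.null(bundle)) {
    if (!simulate)
      stop("stage input: no bundle given and simulate = FALSE ",
           "(missing input tables)")
    bundle <- generateBundle(config)
  }
  if (is.null(bundle$config)) bundle$config <- config
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outDir, name)
    writer(path)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  stage("validate", {
    findings <- validateBundle(bundle)
    if (nrow(findings))
      stop("bundle inconsistent: ", paste(findings$issue, collapse = "; "))
  })

  reliability <- stage("reliability", runReliability(bundle))
  emit("reliability.csv", function(p)
    utils::write.csv(reliability, p, row.names = FALSE))

  pmca <- stage("mca", computePmca(bundle))
  emit("mca.csv", function(p) utils::write.csv(
    data.frame(excerpt = rownames(pmca), pmca, check.names = FALSE), p,
    row.names = FALSE))
  emca <- stage("emca", computeEmca(bundle))
  emit("emca.csv", function(p) utils::write.csv(
    data.frame(excerpt = rownames(emca), emca, check.names = FALSE), p,
    row.names = FALSE))

  affect <- stage("parafac_joint", jointAffectFit(bundle))
  for (mm in c("A", "B", "C")) {
    m <- slot(affect$model, mm)
    emit(sprintf("parafac_%s.csv", mm), function(p) utils::write.csv(
      data.frame(id = rownames(m), m, check.names = FALSE), p,
      row.names = FALSE))
  }
  fitStats <- list(
    R = affect$model@R, sse = affect$model@sse,
    varianceExplained = affect$model@varianceExplained,
    corcondia = corcondia(affect$tensor, affect$model),
    iterations = affect$model@nIter, converged = affect$model@converged)
  emit("fit.json", function(p) jsonlite::write_json(
    fitStats, p, auto_unbox = TRUE, digits = NA))

  if (scree) {
    d <- dim(affect$tensor@values)
    rng <- 2:min(10L, d)
    pf <- bundle$config$parafac
    tab <- stage("scree", screeCp(affect$tensor, rng, nStarts = pf$nStarts,
                                  tol = pf$tol, maxIter = pf$maxIter,
                                  seed = pf$seed))
    emit("scree.csv", function(p) utils::write.csv(tab, p, row.names = FALSE))
  }

  perceptual <- stage("parafac_perceptual", perceptualFactorFit(bundle))

  featurePmca <- stage("feature_pmca", runFeaturePmcaAnalysis(bundle, pmca = pmca))
  emit("feature_pmca.csv", function(p) writeReport(featurePmca, p))
  emotionPmca <- stage("emotion_pmca", runEmotionPmcaAnalysis(bundle, pmca = pmca))
  emit("emotion_pmca.csv", function(p) writeReport(emotionPmca, p))
  factorPmca <- stage("factor_pmca", correlationMatrix(
    affect$musicScores, pmca, correction = bundle$config$correction,
    tail = "two"))
  emit("factor_pmca.csv", function(p) writeReport(factorPmca, p))

  emcaMediation <- stage("emca_mediation", runEmcaMediation(bundle))
  emit("emca_mediation.csv", function(p) writeReport(emcaMediation, p))

  factorEmca <- stage("factor_emca", {
    pemca <- mcaWithFactorAttributes(bundle$choices, affect$colorScores,
                                     weights = bundle$config$mcaWeights)
    pv <- scoreValues(pemca)[rownames(affect$musicScores), , drop = FALSE]
    res <- lapply(colnames(pv), function(f)
      spearmanRho(affect$musicScores[, f], pv[, f],
                  tail = bundle$config$emcaTail))
    entries <- data.frame(
      x = colnames(pv), y = paste0("ParafacEMCA:", colnames(pv)),
      rho = vapply(res, `[[`, 0, "rho"), n = vapply(res, `[[`, 0, "n"),
      p = vapply(res, `[[`, 0, "p"), tail = bundle$config$emcaTail,
      covariates = "", stringsAsFactors = FALSE)
    entries$p_adjusted <- adjustPvalues(entries$p, "bonferroni")
    new("CorrelationReport",
        entries = entries[, c("x", "y", "rho", "n", "p", "p_adjusted",
                              "tail", "covariates")],
        method = "spearman", correction = "bonferroni")
  })
  emit("factor_emca.csv", function(p) writeReport(factorEmca, p))

  partialEmca <- stage("feature_pmca_partial_emca", runPartialling(bundle, "emca_scales", pmca = pmca))
  emit("feature_pmca_partial_emca.csv", function(p) writeReport(partialEmca$after, p))
  partialFactors <- stage("feature_pmca_partial_factors", runPartialling(
    bundle, "factor_scores", musicFactorScores = affect$musicScores,
    pmca = pmca))
  emit("feature_pmca_partial_factors.csv", function(p) writeReport(partialFactors$after, p))

  mlrCmp <- stage("mlr_comparison", runMlrComparison(
    bundle, affectScores = affect$musicScores,
    perceptualScores = perceptual$scores, pmca = pmca))
  emit("mlr_comparison.csv", function(p)
    utils::write.csv(mlrCmp$partitions, p, row.names = FALSE))

  summary <- c(
    sprintf("significant feature x PMCA before partialling: %d",
            partialEmca$nSigBefore),
    sprintf("significant after partialling EMCAs: %d", partialEmca$nSigAfter),
    sprintf("significant after partialling affect factors: %d",
            partialFactors$nSigAfter),
    sprintf("joint Parafac variance explained: %.1f%%",
            100 * affect$model@varianceExplained),
    sprintf("mean R2: affective %.3f vs perceptual %.3f",
            mlrCmp$summary$meanR2Total[mlrCmp$summary$pair == "affective"],
            mlrCmp$summary$meanR2Total[mlrCmp$summary$pair == "perceptual"]))
  emit("summary.txt", function(p) writeLines(summary, p))

  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(unclass(bundle$config), cfgPath)
  outputs <- c(outputs, cfgPath)
  manifest <- list(
    configHash = unname(tools::md5sum(cfgPath)),
    seeds = list(synthetic = bundle$config$synthetic$seed,
                 parafac = bundle$config$parafac$seed),
    stages = c("validate", "reliability", "mca", "parafac_joint",
               if (scree) "scree", "parafac_perceptual", "feature_pmca", "emotion_pmca",
               "factor_pmca", "emca_mediation", "factor_emca", "feature_pmca_partial_emca", "feature_pmca_partial_factors", "mlr_comparison"),
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
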
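#' @include AllClasses.R config.R data_io.R
NULL

anglesToLoadings <- function(degrees) {
  cbind(arousal = cos(degrees * pi / 180), valence = sin(degrees * pi / 180))
}

# fixed substantive orientations of the default inventories in affect space
# (arousal = 0 degrees, valence = 90 degrees); reversed-polarity scales sit
# near 180 degrees
defaultScaleAngles <- function(n) {
  if (n == 10L) c(0, 10, 350, 15, 160, 185, 170, 90, 100, 75)
  else seq(0, 360, length.out = n + 1L)[seq_len(n)]
}

defaultFeatureAngles <- function(n) {
  if (n == 15L) c(5, 20, 355, 10, 345, 15, 330, 25, 40, 60, 80, 110, 200,
                  250, 300)
  else seq(0, 360, length.out = n + 1L)[seq_len(n)]
}

#' Construct the planted latent structure of a synthetic study
#'
#' Draws the generative truth a synthetic bundle is built from: stimulus
#' positions in the two-dimensional affect plane (arousal, valence), fixed
#' substantive loadings of the emotion scales and music-perceptual features
#' on affect, strictly positive subject saliences, the affect-to-appearance
#' map, and the direct-regime perceptual map. Everything downstream is a
#' deterministic function of this object.
#'
#' Defaults mirror the target study design: 37 colors, 34 excerpts, 30
#' subjects, 10 emotion scales, 15 features, ratings on a +/-100 line-mark
#' bound, rating noise 0.15 x bound. Stimulus affect coordinates are
#' uniform on +/- `affectScale` x bound; saliences are log-normal with
#' median 1 (arousal column scaled x1.3, mirroring the tendency to weight
#' arousal more heavily). In the direct regime each feature feeds one
#' color-appearance dimension (round-robin, alternating sign) and four
#' "marker" features — one per appearance dimension — carry a large
#' affect-independent component, so a direct channel is statistically
#' detectable at 34 excerpts.
#'
#' @param nColors,nExcerpts,nSubjects,nScales,nFeatures design sizes.
#' @param bound rating half-range (default 100).
#' @param noiseSd rating noise sd (default `0.15 * bound`).
#' @param choiceTemperature Gumbel noise scale of the choice process.
#' @param mode `"mediated"` or `"direct"`.
#' @param saliencesSdLog log-sd of the subject saliences (0 = all equal).
#' @param affectScale stimulus affect half-range as a fraction of `bound`.
#' @param seed master integer seed.
#' @return a [GenerativeTruth-class].
#' @export
makeGenerativeTruth <- function(nColors = 37L, nExcerpts = 34L,
                                nSubjects = 30L, nScales = 10L,
                                nFeatures = 15L, bound = 100,
                                noiseSd = 0.15 * bound,
                                choiceTemperature = 10,
                                mode = c("mediated", "direct"),
                                saliencesSdLog = 0.4, affectScale = 0.6,
                                seed = 1L) {
  mode <- match.arg(mode)
  seed <- as.integer(seed)
  colorAffect <- withSeed(seed, matrix(
    stats::runif(nColors * 2L, -affectScale * bound, affectScale * bound),
    nColors, 2L, dimnames = list(NULL, c("arousal", "valence"))))
  musicAffect <- withSeed(seed + 1L, matrix(
    stats::runif(nExcerpts * 2L, -affectScale * bound, affectScale * bound),
    nExcerpts, 2L, dimnames = list(NULL, c("arousal", "valence"))))
  saliences <- withSeed(seed + 2L, matrix(
    stats::rlnorm(nSubjects * 2L, meanlog = 0, sdlog = saliencesSdLog),
    nSubjects, 2L, dimnames = list(NULL, c("arousal", "valence"))))
  saliences[, "arousal"] <- 1.3 * saliences[, "arousal"]

  nMarkers <- min(4L, nFeatures)
  featureUniqueSd <- rep(0.15 * bound, nFeatures)
  featureUniqueSd[seq_len(nMarkers)] <- 0.4 * bound
  perceptualMap <- matrix(0, nFeatures, 4L)
  for (j in seq_len(nFeatures))
    perceptualMap[j, ((j - 1L) %% 4L) + 1L] <- if (j %% 2L) 1 else -1
  colnames(perceptualMap) <- appearanceDimensions()

  appearanceMap <- rbind(
    arousal = c(0.8, -0.5, 0.8, 0),
    valence = c(0.3, 0.5, 0, 0.8))
  colnames(appearanceMap) <- appearanceDimensions()

  new("GenerativeTruth", mode = mode, colorAffect = colorAffect,
      musicAffect = musicAffect,
      scaleLoadings = anglesToLoadings(defaultScaleAngles(nScales)),
      subjectSaliences = saliences,
      featureLoadings = anglesToLoadings(defaultFeatureAngles(nFeatures)),
      featureUniqueSd = featureUniqueSd, appearanceMap = appearanceMap,
      appearanceUniqueSd = 0.2 * bound, perceptualMap = perceptualMap,
      noiseSd = noiseSd, choiceTemperature = choiceTemperature,
      bound = bound, seed = seed)
}

#' Generate a ratings tensor from planted trilinear structure
#'
#' Rating model: \deqn{z_{ijk} = clip\big(\sum_r affect_{ir} \,
#' loading_{jr} \, salience_{kr} + u_{ij}\,\bar s_k + \epsilon_{ijk},
#' \pm bound\big)} with i.i.d. Gaussian noise of sd `truth@noiseSd` and
#' clipping at the rating bound (mirroring a bounded line-mark response).
#' An optional stimulus x scale `uniqueSignal` adds affect-independent
#' structure shared across subjects (scaled by each subject's mean
#' salience), used for idiosyncratic music-feature and color-appearance
#' components.
#'
#' @param truth a [GenerativeTruth-class].
#' @param stimuli a [StimulusSet-class]; by default its modality selects the
#'   planted affect matrix (`color` or `music`).
#' @param scales bipolar-scale table ([bipolarScales()]), one row per
#'   loading row.
#' @param subjects subject labels, one per salience row.
#' @param affect optional explicit stimulus x 2 affect matrix.
#' @param loadings optional explicit scales x 2 loading matrix (defaults to
#'   `truth@scaleLoadings`).
#' @param saliences optional explicit subjects x 2 positive salience matrix
#'   (defaults to `truth@subjectSaliences`).
#' @param uniqueSignal optional stimulus x scale matrix of
#'   affect-independent signal.
#' @param seed integer seed for the noise draws (default `truth@seed`);
#'   fixed seed implies a bit-identical tensor.
#' @return a [RatingsTensor-class].
#' @export
generateRatings <- function(truth, stimuli, scales, subjects, affect = NULL,
                            loadings = NULL, saliences = NULL,
                            uniqueSignal = NULL, seed = truth@seed) {
  if (is.null(affect))
    affect <- switch(stimuli@modality,
                     color = truth@colorAffect,
                     music = truth@musicAffect,
                     stop("cannot infer affect for modality ",
                          stimuli@modality))
  if (is.null(loadings)) loadings <- truth@scaleLoadings
  if (is.null(saliences)) saliences <- truth@subjectSaliences
  nI <- length(stimuli@ids); nJ <- nrow(scales); nK <- length(subjects)
  if (nrow(affect) != nI) stop("affect rows must match the stimulus count")
  if (nrow(loadings) != nJ) stop("loading rows must match the scale count")
  if (nrow(saliences) != nK)
    stop("salience rows must match the subject count")
  if (any(saliences <= 0)) stop("saliences must be strictly positive")
  if (!is.null(uniqueSignal) &&
      !identical(dim(uniqueSignal), c(nI, nJ)))
    stop("uniqueSignal must be stimuli x scales")

  gain <- rowMeans(saliences)
  Z <- array(0, dim = c(nI, nJ, nK))
  for (k in seq_len(nK)) {
    sig <- affect %*% (t(loadings) * saliences[k, ])
    if (!is.null(uniqueSignal)) sig <- sig + uniqueSignal * gain[k]
    Z[, , k] <- sig
  }
  if (truth@noiseSd > 0)
    Z <- Z + withSeed(seed, array(stats::rnorm(length(Z),
                                               sd = truth@noiseSd), dim(Z)))
  bnd <- rep(rep(scales$bound, each = nI), times = nK)
  Z <- array(pmin(pmax(as.vector(Z), -bnd), bnd), dim = dim(Z))
  RatingsTensor(Z, stimuli, scales, subjects)
}

gumbel <- function(n) -log(-log(stats::runif(n)))

#' Generate best/worst color choices under a planted regime
#'
#' For every (subject, excerpt) a utility is computed per color and the
#' three highest-utility colors become best1..best3 (descending), the three
#' lowest worst1..worst3 (ascending from the worst) — all six distinct by
#' construction. Utilities get additive Gumbel noise scaled by
#' `truth@choiceTemperature` (the softmax-equivalent discrete-choice model).
#'
#' * `mediated`: utility is the negative salience-weighted Euclidean
#'   distance between the excerpt's and the color's planted affect
#'   positions — subjects match music to colors through shared emotion.
#' * `direct`: the excerpt's feature vector is pushed through the
#'   perceptual map to a target appearance profile (unit-normalized), and
#'   utility is its inner product with the color's appearance vector —
#'   music maps to color looks with no affect involvement.
#'
#' @param truth a [GenerativeTruth-class].
#' @param colorAttributes colors x 4 matrix of (noiseless) color-appearance
#'   values, rownames = color ids.
#' @param musicFeatures excerpts x features matrix of (noiseless) music
#'   feature values; required in direct mode.
#' @param subjects subject labels (one per salience row).
#' @param excerptIds excerpt labels (one per music-affect row).
#' @param seed integer seed (default `truth@seed`); fixed seed implies an
#'   identical table.
#' @return a [ChoiceTable-class].
#' @export
generateChoices <- function(truth, colorAttributes, musicFeatures = NULL,
                            subjects, excerptIds, seed = truth@seed) {
  nC <- nrow(truth@colorAffect)
  nE <- nrow(truth@musicAffect)
  nK <- length(subjects)
  if (nC < 6L) stop("need at least 6 colors to fill the six choice slots")
  if (nrow(colorAttributes) != nC)
    stop("colorAttributes must have one row per color")
  if (length(excerptIds) != nE)
    stop("excerptIds must have one label per excerpt")
  if (nrow(truth@subjectSaliences) != nK)
    stop("subjects must match the salience rows")
  colorIds <- rownames(colorAttributes)
  if (is.null(colorIds)) stop("colorAttributes needs color id rownames")

  if (truth@mode == "direct") {
    if (is.null(musicFeatures)) stop("direct mode requires musicFeatures")
    if (nrow(musicFeatures) != nE || ncol(musicFeatures) !=
        nrow(truth@perceptualMap))
      stop("musicFeatures must be excerpts x features")
    target <- musicFeatures %*% truth@perceptualMap      # excerpts x 4
    norms <- sqrt(rowSums(target^2))
    norms[norms == 0] <- 1
    target <- target / norms
  }

  withSeed(seed, {
    out <- vector("list", nK * nE)
    idx <- 0L
    for (k in seq_len(nK)) {
      sal <- truth@subjectSaliences[k, ]
      for (e in seq_len(nE)) {
        base <- if (truth@mode == "mediated") {
          diff <- sweep(truth@colorAffect, 2L, truth@musicAffect[e, ])
          -sqrt(diff^2 %*% sal)[, 1L]
        } else {
          as.vector(colorAttributes %*% target[e, ])
        }
        u <- base + truth@choiceTemperature * gumbel(nC)
        ord <- order(u, decreasing = TRUE)
        idx <- idx + 1L
        out[[idx]] <- data.frame(
          subject = subjects[k], excerpt = excerptIds[e],
          slot = CHOICE_SLOTS,
          color = colorIds[c(ord[1:3], rev(ord)[1:3])],
          stringsAsFactors = FALSE)
      }
    }
    ChoiceTable(do.call(rbind, out))
  })
}

#' Generate a complete synthetic study bundle
#'
#' Produces the five tables of the study from one [GenerativeTruth-class]:
#' color-emotion ratings (37 colors x 10 scales x 30 subjects),
#' music-emotion ratings (34 x 10 x 30, same subjects), music-perceptual
#' ratings by an independent group of musicians (34 x 15 x 15),
#' color-appearance ratings by an independent rater group (37 x 4 x 48),
#' and the best/worst choice table. The affect-independent ("unique")
#' components of the feature and appearance tables are drawn once and
#' shared between the rating tensors and the choice process, as they would
#' be in a real study where both observe the same stimuli.
#'
#' @param config an [analysisConfig()] (its `$synthetic` block parametrizes
#'   the truth), or a bare synthetic parameter list.
#' @param truth optionally a pre-built [GenerativeTruth-class] (overrides
#'   the config's truth parameters).
#' @return named list: the four [RatingsTensor-class] tables, `choices`,
#'   the stimulus sets `colors`/`excerpts`, `featureSignal` and
#'   `appearanceSignal` (the noiseless per-stimulus tables the choices saw),
#'   `truth`, and `config`. Passes [validateBundle()] with zero findings.
#' @examples
#' b <- generateBundle(analysisConfig(synthetic = list(
#'   nSubjects = 4L, nColors = 10L, nExcerpts = 8L, seed = 7L)))
#' nrow(validateBundle(b))  # 0
#' @export
generateBundle <- function(config = analysisConfig(), truth = NULL) {
  if (!inherits(config, "emomediateConfig"))
    config <- analysisConfig(synthetic = config)
  sy <- config$synthetic
  if (is.null(truth)) {
    truth <- makeGenerativeTruth(
      nColors = sy$nColors, nExcerpts = sy$nExcerpts,
      nSubjects = sy$nSubjects, nScales = sy$nScales,
      nFeatures = sy$nFeatures, bound = sy$bound, noiseSd = sy$noiseSd,
      choiceTemperature = sy$choiceTemperature, mode = sy$mode,
      saliencesSdLog = sy$saliencesSdLog, seed = sy$seed)
  }
  seed <- truth@seed
  nColors <- nrow(truth@colorAffect)
  nExcerpts <- nrow(truth@musicAffect)
  nSubjects <- nrow(truth@subjectSaliences)
  nScales <- nrow(truth@scaleLoadings)
  nFeatures <- nrow(truth@featureLoadings)
  nMusicians <- if (is.null(sy$nMusicians)) 15L else sy$nMusicians
  nRaters <- if (is.null(sy$nAppearanceRaters)) 48L else sy$nAppearanceRaters

  colors <- defaultColorSet(nColors)
  excerpts <- defaultMusicSet(nExcerpts)
  emotionScales <- bipolarScales(defaultEmotionScales(nScales), truth@bound)
  featureScales <- bipolarScales(defaultMusicFeatures(nFeatures),
                                 truth@bound)
  appearScales <- bipolarScales(appearanceDimensions(), truth@bound)
  subjects <- sprintf("S%02d", seq_len(nSubjects))
  musicians <- sprintf("B%02d", seq_len(nMusicians))
  raters <- sprintf("C%02d", seq_len(nRaters))

  colorEmotion <- generateRatings(truth, colors, emotionScales, subjects,
                                  seed = seed + 11L)
  musicEmotion <- generateRatings(truth, excerpts, emotionScales, subjects,
                                  seed = seed + 12L)

  U <- withSeed(seed + 13L, matrix(
    stats::rnorm(nExcerpts * nFeatures,
                 sd = rep(truth@featureUniqueSd, each = nExcerpts)),
    nExcerpts, nFeatures))
  featureSignal <- truth@musicAffect %*% t(truth@featureLoadings) + U
  dimnames(featureSignal) <- list(excerpts@ids, featureScales$name)
  musicianSal <- withSeed(seed + 14L, matrix(
    stats::rlnorm(nMusicians * 2L, sdlog = 0.2), nMusicians, 2L))
  musicFeatures <- generateRatings(truth, excerpts, featureScales, musicians,
                                   loadings = truth@featureLoadings,
                                   saliences = musicianSal, uniqueSignal = U,
                                   seed = seed + 15L)

  V <- withSeed(seed + 16L, matrix(
    stats::rnorm(nColors * 4L, sd = truth@appearanceUniqueSd), nColors, 4L))
  appearanceSignal <- truth@colorAffect %*% truth@appearanceMap + V
  dimnames(appearanceSignal) <- list(colors@ids, appearScales$name)
  raterSal <- withSeed(seed + 17L, matrix(
    stats::rlnorm(nRaters * 2L, sdlog = 0.2), nRaters, 2L))
  colorAppearance <- generateRatings(truth, colors, appearScales, raters,
                                     loadings = t(truth@appearanceMap),
                                     saliences = raterSal, uniqueSignal = V,
                                     seed = seed + 18L)

  choices <- generateChoices(truth, appearanceSignal, featureSignal,
                             subjects, excerpts@ids, seed = seed + 19L)

  list(colorEmotion = colorEmotion, musicEmotion = musicEmotion,
       musicFeatures = musicFeatures, colorAppearance = colorAppearance,
       choices = choices, colors = colors, excerpts = excerpts,
       featureSignal = featureSignal, appearanceSignal = appearanceSignal,
       truth = truth, config = config)
}
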
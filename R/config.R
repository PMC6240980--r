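#' @include AllClasses.R
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  if (!is.null(globalenv()$.Random.seed)) {
    old <- globalenv()$.Random.seed
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed))
  expr
}

#' Build a bipolar-scale table from "pos/neg" names
#'
#' Each scale is a continuous line-mark rating between two opposed poles,
#' encoded numerically on `[-bound, +bound]` with the positive pole positive.
#'
#' @param names character vector of scale names of the form `"pos/neg"`,
#'   e.g. `"happy/sad"`.
#' @param bound positive half-range of the rating scale (default 100).
#' @return data.frame with columns `name`, `positive`, `negative`, `bound`.
#' @examples
#' bipolarScales(c("happy/sad", "warm/cool"))
#' @export
bipolarScales <- function(names, bound = 100) {
  stopifnot(length(names) > 0, bound > 0)
  parts <- strsplit(names, "/", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 2L || any(!nzchar(p)) ||
                  p[1L] == p[2L], logical(1L))
  if (any(bad))
    stop("scale names must be 'pos/neg' with distinct nonempty poles: ",
         paste(names[bad], collapse = ", "))
  data.frame(name = names,
             positive = vapply(parts, `[`, "", 1L),
             negative = vapply(parts, `[`, "", 2L),
             bound = bound,
             stringsAsFactors = FALSE)
}

#' Default stimulus inventories, scales and features
#'
#' The study design these tools target: a 37-color palette (8 hues x 4
#' saturation/lightness cuts plus 5 achromatics), 34 musical excerpts from
#' distinct genres, 10 bipolar emotion-related scales, 15 music-perceptual
#' features, and 4 color-appearance dimensions. Sizes other than the
#' defaults get generic generated labels.
#'
#' @param n number of stimuli/labels wanted.
#' @return a [StimulusSet-class] (stimulus functions) or character vector.
#' @name defaultDesign
NULL

#' @rdname defaultDesign
#' @export
defaultColorSet <- function(n = 37) {
  if (n == 37) {
    hues <- c("R", "O", "Y", "H", "G", "C", "B", "P")
    cuts <- c("S", "L", "M", "D")
    ids <- as.vector(outer(cuts, hues, paste0))
    ids <- c(ids, "WH", "A_L", "A_M", "A_D", "BK")
    meta <- data.frame(
      hue = c(rep(hues, each = 4L), rep("A", 5L)),
      cut = c(rep(cuts, times = 8L), "WH", "L", "M", "D", "BK"),
      stringsAsFactors = FALSE)
    StimulusSet(ids, "color", meta)
  } else {
    StimulusSet(sprintf("C%02d", seq_len(n)), "color")
  }
}

#' @rdname defaultDesign
#' @export
defaultMusicSet <- function(n = 34) {
  genres <- c("Blues", "Salsa", "HeavyMetal", "HipHop", "Jazz", "Country",
              "Arabic", "Ska", "Indie", "Gamelan", "Piano", "Mozart", "Bach",
              "Stravinsky", "Reggae", "Funk", "Disco", "Techno", "Ambient",
              "Bluegrass", "Flamenco", "Klezmer", "Tango", "Samba", "Celtic",
              "Surf", "Swing", "NewAge", "Afrobeat", "Bossa", "Dub", "Polka",
              "Raga", "Zydeco")
  if (n == 34) {
    StimulusSet(sprintf("M%02d", 1:34), "music",
                data.frame(genre = genres, stringsAsFactors = FALSE))
  } else {
    StimulusSet(sprintf("M%02d", seq_len(n)), "music")
  }
}

#' @rdname defaultDesign
#' @export
defaultEmotionScales <- function(n = 10) {
  base <- c("agitated/calm", "spicy/bland", "loud/quiet", "complex/simple",
            "appealing/disgusting", "harmonious/dissonant", "like/dislike",
            "happy/sad", "whimsical/serious", "warm/cool")
  if (n == 10) base else sprintf("posE%02d/negE%02d", seq_len(n), seq_len(n))
}

#' @rdname defaultDesign
#' @export
defaultMusicFeatures <- function(n = 15) {
  base <- c("loud/soft", "fast/slow", "distorted/clear", "electric/acoustic",
            "heavy/light", "punchy/smooth", "low/high", "dense/sparse",
            "strongbeat/weakbeat", "manyinstruments/fewinstruments",
            "rhythmic/arrhythmic", "staccato/legato", "dynamic/flat",
            "intense/mellow", "dissonant/consonant")
  if (n == 15) base else sprintf("posF%02d/negF%02d", seq_len(n), seq_len(n))
}

#' @rdname defaultDesign
#' @export
appearanceDimensions <- function() {
  c("saturated/desaturated", "light/dark", "red/green", "yellow/blue")
}

#' Assemble and validate an analysis configuration
#'
#' Collects every tunable parameter of the pipeline: the six best/worst slot
#' weights of the MCA scoring formula, the Parafac fitting options, the
#' multiple-comparison and tail conventions, and the synthetic-bundle
#' parameters.
#'
#' @param mcaWeights six reals named by choice slot; must sum to 0 with
#'   nonzero absolute mass. Default `(+3, +2, +1, -3, -2, -1)` over
#'   (best1..best3, worst1..worst3); scores divide by `sum(abs(w))`.
#' @param parafac list: `nFactors`, `nStarts`, `tol`, `maxIter`, `seed`,
#'   `nonnegC`.
#' @param correction `"holm"` or `"bonferroni"` for matrix families.
#' @param emcaTail tail of the matched-scale EMCA tests (`"greater"` =
#'   one-tailed positive, the convention for mediation tests).
#' @param synthetic list of generator parameters; see [makeGenerativeTruth()].
#' @return a validated named list of class `emomediateConfig`.
#' @examples
#' cfg <- analysisConfig()
#' cfg$synthetic$nSubjects
#' @export
analysisConfig <- function(mcaWeights = c(best1 = 3, best2 = 2, best3 = 1,
                                          worst1 = -3, worst2 = -2,
                                          worst3 = -1),
                           parafac = list(),
                           correction = "holm",
                           emcaTail = "greater",
                           synthetic = list()) {
  pf <- utils::modifyList(
    list(nFactors = 2L, nStarts = 10L, tol = 1e-8, maxIter = 500L,
         seed = 1L, nonnegC = FALSE), parafac)
  sy <- utils::modifyList(
    list(nColors = 37L, nExcerpts = 34L, nSubjects = 30L, nScales = 10L,
         nFeatures = 15L, nMusicians = 15L, nAppearanceRaters = 48L,
         bound = 100, noiseSd = 15, choiceTemperature = 10,
         mode = "mediated", saliencesSdLog = 0.4, seed = 1L), synthetic)
  if (!identical(sort(names(mcaWeights)), sort(CHOICE_SLOTS)))
    stop("mcaWeights must be named by the six choice slots")
  if (abs(sum(mcaWeights)) > 1e-12)
    stop("mcaWeights must sum to 0")
  if (sum(abs(mcaWeights)) <= 0)
    stop("mcaWeights must have positive absolute mass")
  if (pf$nFactors < 1L) stop("parafac$nFactors must be >= 1")
  if (pf$tol <= 0) stop("parafac$tol must be > 0")
  if (!correction %in% c("holm", "bonferroni"))
    stop("correction must be 'holm' or 'bonferroni'")
  if (!sy$mode %in% c("mediated", "direct"))
    stop("synthetic$mode must be 'mediated' or 'direct'")
  structure(list(mcaWeights = mcaWeights[CHOICE_SLOTS], parafac = pf,
                 correction = correction, emcaTail = emcaTail,
                 synthetic = sy),
            class = "emomediateConfig")
}

#' Read an analysis configuration from YAML
#'
#' The YAML file may contain any subset of the [analysisConfig()] arguments;
#' missing entries fall back to defaults and the merged configuration is
#' validated.
#'
#' @param path path to a YAML file.
#' @return validated configuration list.
#' @export
readAnalysisConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$mcaWeights)) args$mcaWeights <- unlist(y$mcaWeights)
  if (!is.null(y$parafac)) args$parafac <- y$parafac
  if (!is.null(y$correction)) args$correction <- y$correction
  if (!is.null(y$emcaTail)) args$emcaTail <- y$emcaTail
  if (!is.null(y$synthetic)) args$synthetic <- y$synthetic
  do.call(analysisConfig, args)
}
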
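#' @import methods
NULL

CHOICE_SLOTS <- c("best1", "best2", "best3", "worst1", "worst2", "worst3")

#' StimulusSet: an ordered inventory of stimuli
#'
#' Holds the ordered, unique identifiers of one modality's stimuli (the
#' 37-color palette or the 34 musical excerpts) together with per-stimulus
#' metadata such as hue/cut codes or genre labels.
#'
#' @slot ids character vector of unique, nonempty stimulus labels.
#' @slot modality single string, `"color"`, `"music"`, or `"joint"` for the
#'   stacked color+music stimulus mode of the joint emotion tensor.
#' @slot metadata data.frame with one row per stimulus (possibly 0 columns).
#'
#' @examples
#' ss <- StimulusSet(c("SR", "LR"), "color",
#'                   data.frame(hue = c("R", "R"), cut = c("S", "L")))
#' stimulusIds(ss)
#' @export
setClass("StimulusSet",
  representation(ids = "character", modality = "character",
                 metadata = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (length(object@ids) == 0L)
      msg <- c(msg, "ids must be nonempty")
    if (anyDuplicated(object@ids))
      msg <- c(msg, "ids must be unique")
    if (any(!nzchar(object@ids)))
      msg <- c(msg, "ids must be nonempty strings")
    if (length(object@modality) != 1L ||
        !object@modality %in% c("color", "music", "joint"))
      msg <- c(msg, "modality must be one of 'color', 'music', 'joint'")
    if (nrow(object@metadata) != 0L &&
        nrow(object@metadata) != length(object@ids))
      msg <- c(msg, "metadata must have one row per stimulus")
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn StimulusSet-class Constructor.
#' @param ids,modality,metadata see slots.
#' @export
StimulusSet <- function(ids, modality, metadata = data.frame()) {
  new("StimulusSet", ids = as.character(ids), modality = modality,
      metadata = metadata)
}

#' RatingsTensor: a stimuli x scales x subjects array of bipolar ratings
#'
#' The central three-mode data container. Entry `(i, j, k)` is subject k's
#' rating of stimulus i on bipolar scale j, encoded on `[-bound, +bound]`
#' with the positive pole positive. No missing entries are permitted.
#'
#' @slot values numeric 3-d array, stimuli x scales x subjects, with dimnames.
#' @slot stimuli a [StimulusSet-class].
#' @slot scales data.frame describing the bipolar scales, with columns
#'   `name` ("pos/neg"), `positive`, `negative`, `bound`.
#' @slot subjects character vector of subject labels.
#' @slot standardized logical; `TRUE` after [standardizeTensor()], lifting
#'   the bound check.
#' @export
setClass("RatingsTensor",
  representation(values = "array", stimuli = "StimulusSet",
                 scales = "data.frame", subjects = "character",
                 standardized = "logical"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@values)
    if (length(d) != 3L)
      return("values must be a 3-d array (stimuli x scales x subjects)")
    if (d[1L] != length(object@stimuli@ids))
      msg <- c(msg, "stimulus axis length does not match stimulus ids")
    if (d[2L] != nrow(object@scales))
      msg <- c(msg, "scale axis length does not match scale table")
    if (d[3L] != length(object@subjects))
      msg <- c(msg, "subject axis length does not match subject labels")
    if (anyDuplicated(object@subjects))
      msg <- c(msg, "subject labels must be unique")
    if (anyNA(object@values))
      msg <- c(msg, "ratings may not contain missing values")
    if (!all(c("name", "positive", "negative", "bound") %in%
             colnames(object@scales)))
      msg <- c(msg, "scales must have columns name, positive, negative, bound")
    else {
      if (any(!nzchar(object@scales$positive)) ||
          any(!nzchar(object@scales$negative)) ||
          any(object@scales$positive == object@scales$negative))
        msg <- c(msg, "scale poles must be nonempty and distinct")
      if (any(object@scales$bound <= 0))
        msg <- c(msg, "scale bounds must be positive")
      if (!isTRUE(object@standardized) && is.null(msg)) {
        bnd <- rep(object@scales$bound, each = d[1L])
        if (any(abs(object@values) > rep(bnd, times = d[3L]) + 1e-9))
          msg <- c(msg, "ratings exceed the declared scale bound")
      }
    }
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn RatingsTensor-class Constructor; attaches dimnames from the
#'   labels.
#' @param values,stimuli,scales,subjects,standardized see slots.
#' @export
RatingsTensor <- function(values, stimuli, scales, subjects,
                          standardized = FALSE) {
  dimnames(values) <- list(stimuli@ids, scales$name, subjects)
  new("RatingsTensor", values = values, stimuli = stimuli, scales = scales,
      subjects = as.character(subjects), standardized = standardized)
}

#' ChoiceTable: best/worst color selections per subject and excerpt
#'
#' Records the forced-choice task in which each subject picks, for every
#' musical excerpt, the three colors going best with it (best1..best3, in
#' order) and the three going worst (worst1..worst3). The six colors within
#' one (subject, excerpt) cell are necessarily distinct, because colors
#' disappear from the palette as they are selected.
#'
#' @slot records data.frame with columns `subject`, `excerpt`, `slot`,
#'   `color`; exactly six rows per (subject, excerpt).
#' @export
setClass("ChoiceTable",
  representation(records = "data.frame"),
  validity = function(object) {
    r <- object@records
    msg <- NULL
    need <- c("subject", "excerpt", "slot", "color")
    if (!all(need %in% colnames(r)))
      return("records needs columns subject, excerpt, slot, color")
    if (!all(r$slot %in% CHOICE_SLOTS))
      msg <- c(msg, "slot values must be best1..best3, worst1..worst3")
    key <- paste(r$subject, r$excerpt, sep = "\r")
    tab <- table(key)
    if (any(tab != 6L))
      msg <- c(msg, sprintf("every (subject, excerpt) needs exactly 6 slots; first offender: %s",
                            names(tab)[tab != 6L][1L]))
    dupslot <- anyDuplicated(paste(key, r$slot, sep = "\r"))
    if (dupslot)
      msg <- c(msg, "duplicated slot within a (subject, excerpt)")
    dupcol <- tapply(r$color, key, anyDuplicated)
    if (any(dupcol > 0L))
      msg <- c(msg, sprintf("duplicate color within (subject, excerpt) %s",
                            names(dupcol)[dupcol > 0L][1L]))
    if (is.null(msg)) TRUE else msg
  })

#' @describeIn ChoiceTable-class Constructor.
#' @param records see slot.
#' @export
ChoiceTable <- function(records) {
  records$subject <- as.character(records$subject)
  records$excerpt <- as.character(records$excerpt)
  records$slot <- as.character(records$slot)
  records$color <- as.character(records$color)
  rownames(records) <- NULL
  new("ChoiceTable", records = records)
}

#' McaScores: weighted music-color association scores
#'
#' One row per musical excerpt; one column per color attribute (the four
#' color-appearance dimensions for perceptual MCAs, the ten emotion scales
#' for emotional MCAs, or latent factor weights for Parafac-based EMCAs).
#'
#' @slot values numeric matrix, excerpt x attribute, with dimnames.
#' @slot weights the six slot weights used, named by choice slot.
#' @slot level `"across_subject"` (averaged) or `"per_subject"`.
#' @slot perSubject for `per_subject` level, a 3-d array
#'   excerpt x attribute x subject; otherwise a 0-length array.
#' @export
setClass("McaScores",
  representation(values = "matrix", weights = "numeric", level = "character",
                 perSubject = "array"),
  validity = function(object) {
    msg <- NULL
    if (!identical(sort(names(object@weights)), sort(CHOICE_SLOTS)))
      msg <- c(msg, "weights must be named by the six choice slots")
    if (!object@level %in% c("across_subject", "per_subject"))
      msg <- c(msg, "level must be across_subject or per_subject")
    if (anyNA(object@values)) msg <- c(msg, "scores contain NA")
    if (is.null(msg)) TRUE else msg
  })

#' CpModel: a fitted Parafac (CANDECOMP/PARAFAC) decomposition
#'
#' Trilinear model z[i,j,k] ~ sum_r A[i,r] B[j,r] C[k,r]. Columns of B
#' (scales) and C (subjects) are unit-norm; all scale is absorbed into A
#' (stimuli), so stimulus weights are on the data's own scale.
#'
#' @slot A,B,C numeric factor matrices for stimuli, scales and subjects.
#' @slot R integer number of factors.
#' @slot sse residual sum of squares at convergence.
#' @slot totalSS total sum of squares of the fitted tensor.
#' @slot varianceExplained `1 - sse/totalSS`, in `[0, 1]`.
#' @slot nIter iterations used by the retained (best) start.
#' @slot converged logical.
#' @slot startSeed the RNG seed of the retained start.
#' @slot sseTrace per-iteration SSE of the retained start (non-increasing).
#' @export
setClass("CpModel",
  representation(A = "matrix", B = "matrix", C = "matrix", R = "integer",
                 sse = "numeric", totalSS = "numeric",
                 varianceExplained = "numeric", nIter = "integer",
                 converged = "logical", startSeed = "integer",
                 sseTrace = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@A) != object@R || ncol(object@B) != object@R ||
        ncol(object@C) != object@R)
      msg <- c(msg, "factor matrices must have R columns")
    if (object@varianceExplained < -1e-8 ||
        object@varianceExplained > 1 + 1e-8)
      msg <- c(msg, "varianceExplained must lie in [0, 1]")
    if (is.unsorted(rev(object@sseTrace), strict = FALSE) &&
        any(diff(object@sseTrace) > 1e-8 * object@totalSS))
      msg <- c(msg, "SSE trace must be non-increasing")
    if (is.null(msg)) TRUE else msg
  })

#' JointStimulusIndex: row partition of a joint stimulus mode
#'
#' Bookkeeping for the joint color+music tensor: which rows of the stimulus
#' factor matrix are colors and which are musical excerpts. The two ranges
#' form a disjoint, covering, ordered partition.
#'
#' @slot colorRows,musicRows integer index vectors into the stimulus mode.
#' @export
setClass("JointStimulusIndex",
  representation(colorRows = "integer", musicRows = "integer"),
  validity = function(object) {
    all_rows <- c(object@colorRows, object@musicRows)
    if (length(intersect(object@colorRows, object@musicRows)))
      return("color and music rows must be disjoint")
    if (!identical(all_rows, seq_along(all_rows)))
      return("rows must form an ordered covering partition (colors first)")
    TRUE
  })

#' @describeIn JointStimulusIndex-class Constructor from block sizes.
#' @param nColors,nMusic number of color and music rows (colors stacked
#'   first).
#' @export
JointStimulusIndex <- function(nColors, nMusic) {
  new("JointStimulusIndex", colorRows = seq_len(nColors),
      musicRows = nColors + seq_len(nMusic))
}

#' CorrelationReport: labeled (partial) Spearman correlations
#'
#' @slot entries data.frame with columns `x`, `y`, `rho`, `n`, `p`,
#'   `p_adjusted`, `tail`, `covariates` (comma-separated labels, "" if none).
#' @slot method `"spearman"` or `"partial_spearman"`.
#' @slot correction `"holm"`, `"bonferroni"` or `"none"`.
#' @export
setClass("CorrelationReport",
  representation(entries = "data.frame", method = "character",
                 correction = "character"),
  validity = function(object) {
    e <- object@entries
    msg <- NULL
    need <- c("x", "y", "rho", "n", "p", "p_adjusted", "tail", "covariates")
    if (!all(need %in% colnames(e)))
      return(paste("entries needs columns", paste(need, collapse = ", ")))
    if (nrow(e)) {
      if (any(abs(e$rho) > 1 + 1e-8)) msg <- c(msg, "|rho| > 1")
      if (any(e$p < 0 | e$p > 1)) msg <- c(msg, "p outside [0, 1]")
      if (any(e$p_adjusted + 1e-12 < e$p))
        msg <- c(msg, "adjusted p below raw p")
      if (any(e$n < 3)) msg <- c(msg, "n < 3 entries are not reportable")
    }
    if (!object@method %in% c("spearman", "partial_spearman"))
      msg <- c(msg, "unknown method")
    if (!object@correction %in% c("holm", "bonferroni", "none"))
      msg <- c(msg, "unknown correction")
    if (is.null(msg)) TRUE else msg
  })

#' VariancePartition: hierarchical R-squared decomposition
#'
#' Ordinary least squares with the designated first predictor entered
#' first; `r2Increment` is the gain from adding the second.
#'
#' @slot response response label.
#' @slot firstEntered label of the predictor entered first.
#' @slot r2First,r2Total,r2Increment R-squared components.
#' @slot signs named numeric (+1/-1), coefficient signs in the full model.
#' @export
setClass("VariancePartition",
  representation(response = "character", firstEntered = "character",
                 r2First = "numeric", r2Total = "numeric",
                 r2Increment = "numeric", signs = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@r2First < -1e-8 || object@r2Total > 1 + 1e-8 ||
        object@r2First > object@r2Total + 1e-8)
      msg <- c(msg, "need 0 <= r2First <= r2Total <= 1")
    if (abs(object@r2Increment - (object@r2Total - object@r2First)) > 1e-8)
      msg <- c(msg, "r2Increment must equal r2Total - r2First")
    if (is.null(msg)) TRUE else msg
  })

#' GenerativeTruth: planted latent structure of a synthetic bundle
#'
#' Everything the synthetic-data generator needs, and everything a recovery
#' test needs afterwards: planted arousal/valence positions of the stimuli,
#' emotion-scale loadings, subject saliences, the music-feature loadings and
#' their idiosyncratic (affect-independent) spreads, the color-appearance
#' map, the direct-regime perceptual map, noise levels and the seed.
#'
#' @slot mode `"mediated"` (choices driven by affect distance) or
#'   `"direct"` (choices driven by perceptual feature matching).
#' @slot colorAffect,musicAffect n x 2 matrices of planted arousal/valence.
#' @slot scaleLoadings nScales x 2 loadings of emotion scales on affect.
#' @slot subjectSaliences nSubjects x 2, strictly positive factor saliences.
#' @slot featureLoadings nFeatures x 2 loadings of music-perceptual
#'   features on affect.
#' @slot featureUniqueSd per-feature sd of the affect-independent feature
#'   component.
#' @slot appearanceMap 2 x 4 map from affect to color-appearance dimensions.
#' @slot appearanceUniqueSd sd of affect-independent appearance variation.
#' @slot perceptualMap nFeatures x 4 map used by the direct choice regime.
#' @slot noiseSd rating noise sd (same units as the rating bound).
#' @slot choiceTemperature Gumbel noise scale of the choice process.
#' @slot bound rating half-range.
#' @slot seed integer master seed.
#' @export
setClass("GenerativeTruth",
  representation(mode = "character", colorAffect = "matrix",
                 musicAffect = "matrix", scaleLoadings = "matrix",
                 subjectSaliences = "matrix", featureLoadings = "matrix",
                 featureUniqueSd = "numeric", appearanceMap = "matrix",
                 appearanceUniqueSd = "numeric", perceptualMap = "matrix",
                 noiseSd = "numeric", choiceTemperature = "numeric",
                 bound = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!object@mode %in% c("mediated", "direct"))
      msg <- c(msg, "mode must be 'mediated' or 'direct'")
    if (ncol(object@colorAffect) != 2L || ncol(object@musicAffect) != 2L ||
        ncol(object@scaleLoadings) != 2L ||
        ncol(object@subjectSaliences) != 2L ||
        ncol(object@featureLoadings) != 2L)
      msg <- c(msg, "affect-space matrices must have 2 columns")
    if (any(object@subjectSaliences <= 0))
      msg <- c(msg, "subject saliences must be strictly positive")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@choiceTemperature <= 0)
      msg <- c(msg, "choiceTemperature must be > 0")
    if (nrow(object@perceptualMap) != nrow(object@featureLoadings) ||
        ncol(object@perceptualMap) != 4L)
      msg <- c(msg, "perceptualMap must be nFeatures x 4")
    if (length(object@featureUniqueSd) != nrow(object@featureLoadings))
      msg <- c(msg, "featureUniqueSd must have one entry per feature")
    if (!identical(dim(object@appearanceMap), c(2L, 4L)))
      msg <- c(msg, "appearanceMap must be 2 x 4")
    if (object@bound <= 0) msg <- c(msg, "bound must be > 0")
    if (is.null(msg)) TRUE else msg
  })
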
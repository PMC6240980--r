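#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small read-only accessors so downstream code never touches slots.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("stimulusIds", function(x) standardGeneric("stimulusIds"))
#' @rdname accessors
#' @export
setMethod("stimulusIds", "StimulusSet", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("stimulusIds", "RatingsTensor", function(x) x@stimuli@ids)

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname accessors
#' @export
setMethod("modality", "StimulusSet", function(x) x@modality)

#' @rdname accessors
#' @export
setGeneric("stimulusMetadata", function(x) standardGeneric("stimulusMetadata"))
#' @rdname accessors
#' @export
setMethod("stimulusMetadata", "StimulusSet", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("ratingValues", function(x) standardGeneric("ratingValues"))
#' @rdname accessors
#' @export
setMethod("ratingValues", "RatingsTensor", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("scaleTable", function(x) standardGeneric("scaleTable"))
#' @rdname accessors
#' @export
setMethod("scaleTable", "RatingsTensor", function(x) x@scales)

#' @rdname accessors
#' @export
setGeneric("scaleNames", function(x) standardGeneric("scaleNames"))
#' @rdname accessors
#' @export
setMethod("scaleNames", "RatingsTensor", function(x) x@scales$name)

#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setMethod("subjectIds", "RatingsTensor", function(x) x@subjects)

#' @rdname accessors
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))
#' @rdname accessors
#' @export
setMethod("isStandardized", "RatingsTensor", function(x) x@standardized)

#' @rdname accessors
#' @export
setGeneric("choiceRecords", function(x) standardGeneric("choiceRecords"))
#' @rdname accessors
#' @export
setMethod("choiceRecords", "ChoiceTable", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))
#' @rdname accessors
#' @export
setMethod("scoreValues", "McaScores", function(x) x@values)
#' @rdname accessors
#' @export
setGeneric("scoreLevel", function(x) standardGeneric("scoreLevel"))
#' @rdname accessors
#' @export
setMethod("scoreLevel", "McaScores", function(x) x@level)
#' @rdname accessors
#' @export
setGeneric("weightsUsed", function(x) standardGeneric("weightsUsed"))
#' @rdname accessors
#' @export
setMethod("weightsUsed", "McaScores", function(x) x@weights)
#' @rdname accessors
#' @export
setGeneric("perSubjectScores", function(x) standardGeneric("perSubjectScores"))
#' @rdname accessors
#' @export
setMethod("perSubjectScores", "McaScores", function(x) {
  if (x@level != "per_subject")
    stop("per-subject scores were not retained at this level")
  x@perSubject
})

#' Factor matrix of one CP mode
#'
#' @param x a [CpModel-class].
#' @param mode `"stimuli"` (A), `"scales"` (B), or `"subjects"` (C).
#' @return the numeric factor matrix of that mode.
#' @export
setGeneric("factorMatrix", function(x, mode) standardGeneric("factorMatrix"))
#' @rdname factorMatrix
#' @export
setMethod("factorMatrix", "CpModel", function(x, mode) {
  switch(match.arg(mode, c("stimuli", "scales", "subjects")),
         stimuli = x@A, scales = x@B, subjects = x@C)
})

#' @rdname accessors
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))
#' @rdname accessors
#' @export
setMethod("nFactors", "CpModel", function(x) x@R)

#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(x) standardGeneric("varianceExplained"))
#' @rdname accessors
#' @export
setMethod("varianceExplained", "CpModel", function(x) x@varianceExplained)

#' @rdname accessors
#' @export
setGeneric("residualSS", function(x) standardGeneric("residualSS"))
#' @rdname accessors
#' @export
setMethod("residualSS", "CpModel", function(x) x@sse)

#' @rdname accessors
#' @export
setGeneric("sseTrace", function(x) standardGeneric("sseTrace"))
#' @rdname accessors
#' @export
setMethod("sseTrace", "CpModel", function(x) x@sseTrace)

#' @rdname accessors
#' @export
setGeneric("reportEntries", function(x) standardGeneric("reportEntries"))
#' @rdname accessors
#' @export
setMethod("reportEntries", "CorrelationReport", function(x) x@entries)

#' Significant entries of a correlation report
#'
#' @param x a [CorrelationReport-class].
#' @param alpha significance level applied to the adjusted p-values.
#' @return the subset of entries with `p_adjusted < alpha`.
#' @export
setGeneric("significantEntries",
           function(x, alpha = 0.05) standardGeneric("significantEntries"))
#' @rdname significantEntries
#' @export
setMethod("significantEntries", "CorrelationReport", function(x, alpha = 0.05) {
  x@entries[x@entries$p_adjusted < alpha, , drop = FALSE]
})

setMethod("show", "StimulusSet", function(object) {
  cat(sprintf("StimulusSet of %d %s stimuli (%s%s)\n",
              length(object@ids), object@modality,
              paste(utils::head(object@ids, 4L), collapse = ", "),
              if (length(object@ids) > 4L) ", ..." else ""))
})

setMethod("show", "RatingsTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("RatingsTensor: %d %s stimuli x %d scales x %d subjects%s\n",
              d[1L], object@stimuli@modality, d[2L], d[3L],
              if (object@standardized) " (standardized)" else ""))
})

setMethod("show", "ChoiceTable", function(object) {
  r <- object@records
  cat(sprintf("ChoiceTable: %d subjects x %d excerpts (%d records)\n",
              length(unique(r$subject)), length(unique(r$excerpt)), nrow(r)))
})

setMethod("show", "McaScores", function(object) {
  cat(sprintf("McaScores (%s): %d excerpts x %d attributes [%s]\n",
              object@level, nrow(object@values), ncol(object@values),
              paste(colnames(object@values), collapse = ", ")))
})

setMethod("show", "CpModel", function(object) {
  cat(sprintf(
    "CpModel: R = %d, variance explained = %.1f%%, %d iterations%s\n",
    object@R, 100 * object@varianceExplained, object@nIter,
    if (object@converged) "" else " (not converged)"))
})

setMethod("show", "CorrelationReport", function(object) {
  cat(sprintf("CorrelationReport (%s, %s): %d entries, %d significant at .05\n",
              object@method, object@correction, nrow(object@entries),
              sum(object@entries$p_adjusted < 0.05)))
})

setMethod("show", "VariancePartition", function(object) {
  cat(sprintf("VariancePartition for %s: R2 %.3f (first: %s %.3f, +%.3f)\n",
              object@response, object@r2Total, object@firstEntered,
              object@r2First, object@r2Increment))
})

setMethod("show", "GenerativeTruth", function(object) {
  cat(sprintf(
    "GenerativeTruth (%s): %d colors, %d excerpts, %d subjects, %d scales, %d features; noise sd %.1f, temperature %.1f, seed %d\n",
    object@mode, nrow(object@colorAffect), nrow(object@musicAffect),
    nrow(object@subjectSaliences), nrow(object@scaleLoadings),
    nrow(object@featureLoadings), object@noiseSd, object@choiceTemperature,
    object@seed))
})
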
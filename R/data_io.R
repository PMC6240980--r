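#' @include AllClasses.R config.R
NULL

#' Read a ratings tensor from long-format CSV
#'
#' The interchange format is long CSV with header `stimulus,scale,subject,
#' value` (UTF-8, period decimal separator). The axis order of the returned
#' tensor follows the declared `stimuli`/`scales`/`subjects`, never the file
#' row order, so shuffled files load identically. Every cell must be present
#' exactly once: the study design has no missing data, and a missing or
#' duplicated cell is an error naming the offending
#' (stimulus, scale, subject).
#'
#' @param path CSV file path.
#' @param stimuli a [StimulusSet-class] declaring the stimulus axis.
#' @param scales bipolar-scale table from [bipolarScales()].
#' @param subjects character vector of subject labels. A single label can
#'   represent across-subject averages (subject axis of length 1).
#' @param standardized logical; set `TRUE` when loading standardized values
#'   (lifts the `[-bound, bound]` range check).
#' @return a validated [RatingsTensor-class].
#' @seealso [writeRatings()]
#' @export
loadRatings <- function(path, stimuli, scales, subjects,
                        standardized = FALSE) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("stimulus", "scale", "subject", "value")
  if (!all(need %in% colnames(df)))
    stop("ratings CSV needs columns ", paste(need, collapse = ", "))
  df$subject <- as.character(df$subject)
  unknown <- setdiff(unique(df$stimulus), stimuli@ids)
  if (length(unknown))
    stop("unknown stimulus id(s) in file: ", paste(unknown, collapse = ", "))
  unknown <- setdiff(unique(df$scale), scales$name)
  if (length(unknown))
    stop("unknown scale(s) in file: ", paste(unknown, collapse = ", "))
  unknown <- setdiff(unique(df$subject), as.character(subjects))
  if (length(unknown))
    stop("unknown subject(s) in file: ", paste(unknown, collapse = ", "))

  d <- c(length(stimuli@ids), nrow(scales), length(subjects))
  arr <- array(NA_real_, dim = d)
  i <- match(df$stimulus, stimuli@ids)
  j <- match(df$scale, scales$name)
  k <- match(df$subject, as.character(subjects))
  idx <- cbind(i, j, k)
  dup <- duplicated(idx)
  if (any(dup)) {
    w <- which(dup)[1L]
    stop(sprintf("duplicated cell (%s, %s, %s)", df$stimulus[w],
                 df$scale[w], df$subject[w]))
  }
  arr[idx] <- df$value
  if (anyNA(arr)) {
    miss <- which(is.na(arr), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing cell (%s, %s, %s)", stimuli@ids[miss[1L]],
                 scales$name[miss[2L]], as.character(subjects)[miss[3L]]))
  }
  if (!standardized) {
    bnd <- scales$bound[j]
    bad <- abs(df$value) > bnd + 1e-9
    if (any(bad)) {
      w <- which(bad)[1L]
      stop(sprintf("rating out of range at (%s, %s, %s): %g exceeds bound %g",
                   df$stimulus[w], df$scale[w], df$subject[w], df$value[w],
                   bnd[w]))
    }
  }
  RatingsTensor(arr, stimuli, scales, subjects, standardized = standardized)
}

#' Write a ratings tensor to long-format CSV
#'
#' @param tensor a [RatingsTensor-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRatings <- function(tensor, path) {
  d <- dim(tensor@values)
  df <- data.frame(
    stimulus = rep(tensor@stimuli@ids, times = d[2L] * d[3L]),
    scale = rep(rep(tensor@scales$name, each = d[1L]), times = d[3L]),
    subject = rep(tensor@subjects, each = d[1L] * d[2L]),
    value = as.vector(tensor@values),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a best/worst choice table from CSV
#'
#' Long CSV with header `subject,excerpt,slot,color`; slots are
#' `best1..best3, worst1..worst3`. Enforces the task structure: exactly six
#' slots per (subject, excerpt) and six distinct colors within that cell
#' (selected colors disappeared from the palette), with all ids resolving
#' against the declared stimulus sets.
#'
#' @param path CSV file path.
#' @param colors color [StimulusSet-class].
#' @param excerpts music [StimulusSet-class].
#' @return a validated [ChoiceTable-class].
#' @export
loadChoices <- function(path, colors, excerpts) {
  if (!file.exists(path)) stop("choices file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "excerpt", "slot", "color")
  if (!all(need %in% colnames(df)))
    stop("choices CSV needs columns ", paste(need, collapse = ", "))
  unknown <- setdiff(unique(df$color), colors@ids)
  if (length(unknown))
    stop("unknown color id(s): ", paste(unknown, collapse = ", "))
  unknown <- setdiff(unique(df$excerpt), excerpts@ids)
  if (length(unknown))
    stop("unknown excerpt id(s): ", paste(unknown, collapse = ", "))
  ChoiceTable(df)
}

#' Write a choice table to CSV
#'
#' @param choices a [ChoiceTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeChoices <- function(choices, path) {
  utils::write.csv(choices@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write a color-attribute table (wide CSV)
#'
#' An attribute table is a colors x attributes numeric matrix: the
#' across-subject average color-appearance ratings, the average
#' color-emotion ratings, or latent color factor weights. Wide CSV with a
#' `color` id column and one column per attribute.
#'
#' @param path CSV file path.
#' @param colors color [StimulusSet-class]; rows are reordered to match.
#' @return numeric matrix with color ids as rownames.
#' @export
readAttributeTable <- function(path, colors) {
  if (!file.exists(path)) stop("attribute file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"color" %in% colnames(df))
    stop("attribute CSV needs a 'color' id column")
  if (anyDuplicated(df$color)) stop("duplicated color row in attribute table")
  missing <- setdiff(colors@ids, df$color)
  if (length(missing))
    stop("attribute table misses color(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(df[match(colors@ids, df$color),
                    setdiff(colnames(df), "color"), drop = FALSE])
  rownames(m) <- colors@ids
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("attribute table contains non-numeric or missing cells")
  m
}

#' @rdname readAttributeTable
#' @param attributes colors x attributes matrix with rownames.
#' @export
writeAttributeTable <- function(attributes, path) {
  df <- data.frame(color = rownames(attributes), attributes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate a study bundle
#'
#' Checks id and axis consistency across all tables of a bundle (color- and
#' music-emotion tensors, music-feature tensor, color-appearance tensor,
#' choice table) without mutating anything. Findings are returned as data,
#' never raised: an empty data.frame means the bundle is consistent.
#'
#' @param bundle named list with elements `colorEmotion`, `musicEmotion`,
#'   `musicFeatures`, `colorAppearance` ([RatingsTensor-class]) and
#'   `choices` ([ChoiceTable-class]); see [generateBundle()].
#' @return data.frame with columns `component` and `issue` (0 rows = pass).
#' @export
validateBundle <- function(bundle) {
  findings <- list()
  add <- function(component, issue)
    findings[[length(findings) + 1L]] <<- data.frame(
      component = component, issue = issue, stringsAsFactors = FALSE)

  need <- c("colorEmotion", "musicEmotion", "musicFeatures",
            "colorAppearance", "choices")
  for (nm in setdiff(need, names(bundle))) add("bundle", paste("missing", nm))
  if (length(findings)) return(do.call(rbind, findings))

  colors <- bundle$colorEmotion@stimuli
  excerpts <- bundle$musicEmotion@stimuli
  if (colors@modality != "color")
    add("colorEmotion", "stimuli are not colors")
  if (excerpts@modality != "music")
    add("musicEmotion", "stimuli are not music")
  if (!identical(scaleNames(bundle$colorEmotion),
                 scaleNames(bundle$musicEmotion)))
    add("scales", "color-emotion and music-emotion scale sets differ")
  if (!identical(subjectIds(bundle$colorEmotion),
                 subjectIds(bundle$musicEmotion)))
    add("subjects", "color-emotion and music-emotion subject sets differ")
  if (!identical(stimulusIds(bundle$musicFeatures), excerpts@ids))
    add("musicFeatures", "excerpt ids differ from the music-emotion tensor")
  if (!identical(stimulusIds(bundle$colorAppearance), colors@ids))
    add("colorAppearance", "color ids differ from the color-emotion tensor")

  rec <- bundle$choices@records
  badc <- setdiff(unique(rec$color), colors@ids)
  for (id in badc) add("choices", paste("unknown color id:", id))
  bade <- setdiff(unique(rec$excerpt), excerpts@ids)
  for (id in bade) add("choices", paste("unknown excerpt id:", id))
  bads <- setdiff(unique(rec$subject), subjectIds(bundle$colorEmotion))
  for (id in bads) add("choices", paste("unknown subject:", id))
  missing <- setdiff(excerpts@ids, unique(rec$excerpt))
  for (id in missing) add("choices", paste("no choices for excerpt:", id))

  if (length(findings)) do.call(rbind, findings)
  else data.frame(component = character(), issue = character(),
                  stringsAsFactors = FALSE)
}
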
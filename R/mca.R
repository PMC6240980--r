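#' @include AllClasses.R config.R
NULL

#' Weighted best/worst music-color association scores
#'
#' For each (subject, excerpt) cell, the six chosen colors are aggregated
#' into one score per color attribute:
#' \deqn{score(attr) = \sum_s w_s \, attr(color_s) \; / \; \sum_s |w_s|}
#' with positive weights on the best slots and negative on the worst, so a
#' high score means the best-fitting colors carry high attribute values and
#' the worst-fitting ones low values. Because the weights sum to zero the
#' score is invariant to shifting all attribute values by a constant, and
#' the normalization by \eqn{\sum |w|} keeps scores on the attribute's own
#' rating scale. With the four color-appearance dimensions as attributes
#' these are perceptual MCA (PMCA) scores; with the ten color-emotion
#' averages, emotional MCA (EMCA) scores.
#'
#' @param choices a [ChoiceTable-class].
#' @param attributes colors x attributes numeric matrix (rownames = color
#'   ids) covering every chosen color.
#' @param weights six reals named by slot, summing to 0 with nonzero
#'   absolute mass. Default `(+3, +2, +1, -3, -2, -1)` in slot order
#'   best1..best3, worst1..worst3 (magnitude decreasing in choice order
#'   within best and within worst).
#' @param level `"across_subject"` (plain mean of the per-subject scores)
#'   or `"per_subject"` (retains the per-subject array).
#' @return an [McaScores-class] with one row per excerpt.
#' @examples
#' ch <- ChoiceTable(data.frame(
#'   subject = "s1", excerpt = "M01",
#'   slot = c("best1", "best2", "best3", "worst1", "worst2", "worst3"),
#'   color = paste0("c", 1:6)))
#' attrs <- matrix(c(10, 20, 30, 40, 0, -10), 6, 1,
#'                 dimnames = list(paste0("c", 1:6), "light/dark"))
#' scoreValues(computeMca(ch, attrs))  # (30+40+30-120-0+10)/12 = -0.833
#' @export
computeMca <- function(choices, attributes,
                       weights = c(best1 = 3, best2 = 2, best3 = 1,
                                   worst1 = -3, worst2 = -2, worst3 = -1),
                       level = c("across_subject", "per_subject")) {
  level <- match.arg(level)
  if (!identical(sort(names(weights)), sort(CHOICE_SLOTS)))
    stop("weights must be named by the six choice slots")
  if (abs(sum(weights)) > 1e-12) stop("weights must sum to 0")
  wabs <- sum(abs(weights))
  if (wabs <= 0) stop("sum of absolute weights must be > 0")
  if (is.null(rownames(attributes)) || is.null(colnames(attributes)))
    stop("attributes needs color rownames and attribute colnames")

  rec <- choices@records
  missing <- setdiff(unique(rec$color), rownames(attributes))
  if (length(missing))
    stop("chosen color(s) missing from attribute table: ",
         paste(missing, collapse = ", "))

  subjects <- unique(rec$subject)
  excerpts <- unique(rec$excerpt)
  nA <- ncol(attributes)
  # weight per record, then sum attribute * weight within (excerpt, subject)
  w <- weights[rec$slot] / wabs
  contrib <- attributes[rec$color, , drop = FALSE] * w
  per <- array(0, dim = c(length(excerpts), nA, length(subjects)),
               dimnames = list(excerpts, colnames(attributes), subjects))
  ei <- match(rec$excerpt, excerpts)
  si <- match(rec$subject, subjects)
  for (a in seq_len(nA)) {
    per[, a, ] <- as.matrix(unclass(
      tapply(contrib[, a], list(factor(ei, seq_along(excerpts)),
                                factor(si, seq_along(subjects))), sum,
             default = 0)))
  }
  across <- apply(per, c(1L, 2L), mean)
  new("McaScores",
      values = across,
      weights = weights[CHOICE_SLOTS],
      level = level,
      perSubject = if (level == "per_subject") per
                   else array(numeric(0), dim = c(0L, 0L, 0L)))
}

#' Parafac-based MCA scores from latent color factor weights
#'
#' Identical aggregation formula to [computeMca()], with the color rows of a
#' fitted Parafac stimulus-weight matrix (e.g. arousal/valence weights of
#' the 37 colors) standing in for rated attributes. The result is the
#' Parafac-based emotional MCA score of each excerpt on each latent factor.
#'
#' @param choices a [ChoiceTable-class].
#' @param colorFactorWeights colors x factors matrix (one column per latent
#'   factor; rownames = color ids).
#' @inheritParams computeMca
#' @return an [McaScores-class], excerpts x factors.
#' @export
mcaWithFactorAttributes <- function(choices, colorFactorWeights,
                                    weights = c(best1 = 3, best2 = 2,
                                                best3 = 1, worst1 = -3,
                                                worst2 = -2, worst3 = -1),
                                    level = c("across_subject",
                                              "per_subject")) {
  if (is.null(colnames(colorFactorWeights)))
    colnames(colorFactorWeights) <-
      paste0("factor", seq_len(ncol(colorFactorWeights)))
  computeMca(choices, colorFactorWeights, weights = weights,
             level = match.arg(level))
}
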
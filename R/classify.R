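# Cutoff-based classification of similarity results and its validation.

#' Benjamini-Hochberg data-derived p-value cutoff
#'
#' Sorts the p-values ascending and returns the largest p(i) satisfying
#' p(i) <= (i/m) * alpha — the step-up threshold actually attained on the
#' data. Returns 0 when nothing qualifies. This is the procedure that, on
#' the original validation set, yielded a cutoff of 2e-4 at alpha = 0.001,
#' subsequently rounded to the fixed 1e-4 used by [classifyStatus()].
#'
#' @param pValues Nonempty numeric vector of p-values.
#' @param alpha False discovery rate level (default 0.001).
#' @return The data-derived p-value threshold (0 if none pass).
#' @examples
#' bhCutoff(c(1e-6, 2e-4, 0.03), alpha = 0.001)  # 2e-4
#' @export
bhCutoff <- function(pValues, alpha = 0.001) {
  if (length(pValues) == 0L)
    stop("pValues must be nonempty")
  stopifnot(all(pValues >= 0 & pValues <= 1), alpha > 0)
  p <- sort(pValues)
  m <- length(p)
  pass <- p <= seq_len(m) / m * alpha
  if (!any(pass)) 0 else p[max(which(pass))]
}

.classifyVec <- function(p, dir, cutoff) {
  out <- rep("unchanged", length(p))
  sig <- p <= cutoff
  out[sig & dir == 1L] <- "activated"
  out[sig & dir == -1L] <- "suppressed"
  if (any(sig & dir == 0L))
    warning("significant similarity with indeterminate direction; ",
            "classified as unchanged")
  factor(out, levels = .CLASS_LEVELS)
}

#' Classify a similarity result as activated, suppressed or unchanged
#'
#' A bioset whose similarity p-value passes the cutoff is called
#' \code{"activated"} (masculinized) when the correlation is concordant
#' (+1) and \code{"suppressed"} (feminized) when anticorrelated (-1);
#' everything else is \code{"unchanged"}. A significant result with
#' indeterminate direction is classified unchanged with a warning. The
#' default cutoff 1e-4 is the fixed compendium-screening threshold.
#'
#' @param result A [SimilarityResult-class], or a numeric vector of
#'   p-values (then \code{direction} must be supplied).
#' @param cutoff Similarity p-value cutoff (default 1e-4).
#' @param direction Integer vector in \{-1, 0, +1\} when \code{result} is
#'   numeric.
#' @return A factor with levels activated, suppressed, unchanged.
#' @examples
#' classifyStatus(5e-5, direction = -1L)   # suppressed (feminized)
#' classifyStatus(4e-4, direction = -1L)   # unchanged at 1e-4
#' @export
classifyStatus <- function(result, cutoff = 1e-4, direction = NULL) {
  if (is(result, "SimilarityResult"))
    return(.classifyVec(result@pValue, result@direction, cutoff))
  stopifnot(is.numeric(result), !is.null(direction),
            length(direction) == length(result))
  .classifyVec(result, as.integer(direction), cutoff)
}

#' Balanced accuracy of a one-vs-rest classification
#'
#' Computes 100 * (sensitivity + specificity) / 2 for the binary problem
#' "is the bioset of class \code{positive}?". The positive class must occur
#' in the truth labels. Swapping the roles of positive and negative swaps
#' sensitivity and specificity and leaves the value unchanged.
#'
#' @param truth,predicted Equal-length vectors of class labels.
#' @param positive The class treated as positive (e.g. \code{"suppressed"}).
#' @return Balanced accuracy as a percentage in \[0, 100\].
#' @export
balancedAccuracy <- function(truth, predicted, positive) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  isPos <- truth == positive
  if (!any(isPos))
    stop("positive class '", positive, "' absent from truth labels")
  sens <- mean(predicted[isPos] == positive)
  specif <- if (any(!isPos)) mean(predicted[!isPos] != positive) else NA_real_
  if (is.na(specif))
    stop("no negative examples in truth labels")
  100 * (sens + specif) / 2
}
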
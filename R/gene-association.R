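# Relating single-gene expression changes to classification status, with
# Fisher exact enrichment against the unchanged group.

#' Tabulate a gene's expression changes by classification status
#'
#' For one gene (e.g. Pparg), counts across the master table how many
#' biosets of each classification status show the gene increased
#' (fold-change >= +threshold) or decreased (fold-change <= -threshold).
#' Biosets where the gene is absent or below threshold are excluded
#' entirely — a value of 0 may equally mean "not measured on the platform",
#' so only altered biosets enter the comparison.
#'
#' @param gene Gene identifier (normalized internally).
#' @param master Master table from [buildMasterTable()].
#' @param biosets List of [Bioset-class] objects covering the master rows.
#' @param fcThreshold Minimum absolute fold-change to count as altered
#'   (default 1.5, inclusive).
#' @return \code{data.frame} with one row per status (activated,
#'   suppressed, unchanged) and columns \code{status}, \code{n_increased},
#'   \code{n_decreased}.
#' @export
geneChangeByStatus <- function(gene, master, biosets, fcThreshold = 1.5) {
  stopifnot(is.data.frame(master), is.list(biosets), fcThreshold >= 1)
  gene <- normalizeGene(gene)
  ids <- vapply(biosets, biosetId, character(1))
  counts <- matrix(0L, nrow = 3L, ncol = 2L,
                   dimnames = list(.CLASS_LEVELS,
                                   c("n_increased", "n_decreased")))
  seen <- FALSE
  for (i in seq_len(nrow(master))) {
    j <- match(master$bioset_id[i], ids)
    if (is.na(j)) next
    fc <- foldChanges(biosets[[j]])
    if (!gene %in% names(fc)) next
    seen <- TRUE
    v <- fc[[gene]]
    status <- master$stat5b_call[i]
    if (v >= fcThreshold)
      counts[status, "n_increased"] <- counts[status, "n_increased"] + 1L
    else if (v <= -fcThreshold)
      counts[status, "n_decreased"] <- counts[status, "n_decreased"] + 1L
  }
  if (!seen)
    warning("gene '", gene, "' absent from every bioset")
  data.frame(status = rownames(counts), n_increased = counts[, 1L],
             n_decreased = counts[, 2L], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Fisher exact enrichment of gene changes in one status versus a reference
#'
#' Tests whether the increased/decreased split of the gene differs between
#' a test status group and a reference group (by default the unchanged
#' biosets) with a two-sided Fisher exact test on the 2x2 table
#' \code{[[test increased, test decreased], [ref increased, ref decreased]]}.
#' Significance is flagged with \code{"*"} at p <= 0.05 and \code{"**"} at
#' p <= 0.01.
#'
#' @param counts \code{data.frame} from [geneChangeByStatus()].
#' @param testStatus Status to test (\code{"activated"} or
#'   \code{"suppressed"}).
#' @param referenceStatus Reference status (default \code{"unchanged"}).
#' @return List with \code{p.value}, \code{table} and \code{stars}.
#' @export
enrichmentTest <- function(counts, testStatus,
                           referenceStatus = "unchanged") {
  stopifnot(is.data.frame(counts),
            all(c("status", "n_increased", "n_decreased") %in% names(counts)))
  rows <- match(c(testStatus, referenceStatus), counts$status)
  if (anyNA(rows))
    stop("status not found in counts table")
  tab <- as.matrix(counts[rows, c("n_increased", "n_decreased")])
  dimnames(tab) <- list(c(testStatus, referenceStatus),
                        c("increased", "decreased"))
  if (any(rowSums(tab) == 0))
    stop("both status groups must contain altered biosets")
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  stars <- if (p <= 0.01) "**" else if (p <= 0.05) "*" else ""
  list(p.value = p, table = tab, stars = stars)
}

#' Percentage of altered biosets with the gene increased
#'
#' 100 * increased / (increased + decreased) for one status, rounded to
#' the nearest integer — the denominator counts only biosets in which the
#' gene was altered at all.
#'
#' @param counts \code{data.frame} from [geneChangeByStatus()], or the
#'   increased count directly.
#' @param status Status row to use when \code{counts} is a data frame.
#' @param nDecreased Decreased count when \code{counts} is given as a
#'   number.
#' @return Integer percentage in \[0, 100\].
#' @examples
#' percentIncreased(60, nDecreased = 9)  # 87
#' @export
percentIncreased <- function(counts, status = NULL, nDecreased = NULL) {
  if (is.data.frame(counts)) {
    row <- match(status, counts$status)
    if (is.na(row)) stop("status not found in counts table")
    ni <- counts$n_increased[row]; nd <- counts$n_decreased[row]
  } else {
    ni <- counts; nd <- nDecreased
  }
  if (ni + nd == 0)
    stop("no altered biosets for this status")
  round(100 * ni / (ni + nd))
}
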
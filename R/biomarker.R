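# Biomarker construction from replicate male-vs-female comparisons, the
# knockout-dependence filter, and the residual sex-specific intersection.

#' Select genes consistently dimorphic across replicate comparisons
#'
#' A gene qualifies as a biomarker candidate when (a) it appears — i.e. was
#' statistically significant upstream — in at least \code{minSupport} of the
#' panel's comparisons, (b) its fold-change has the same sign in every
#' comparison where it appears (when \code{requireSameDirection}), and (c)
#' the mean of its fold-changes over the comparisons where it appears has
#' magnitude at least \code{minAvgAbsFC}. The returned fold-change is that
#' mean. Averaging uses only the comparisons where the gene is present;
#' absence is not imputed as no change. The result is sorted by gene id, so
#' it is invariant to comparison order.
#'
#' @param panel A [ComparisonPanel-class] with a nonempty comparison list.
#' @param minSupport Minimum number of comparisons a gene must appear in
#'   (default 4, against the conventional panel of 6).
#' @param requireSameDirection Require an identical fold-change sign
#'   wherever the gene appears (default TRUE).
#' @param minAvgAbsFC Minimum magnitude of the mean fold-change (default
#'   1.5).
#' @return \code{data.frame} with columns \code{gene}, \code{fold_change}
#'   (the mean) and \code{support}, sorted by gene.
#' @seealso [applyDependenceFilter()], [buildBiomarker()]
#' @export
selectConsistentGenes <- function(panel, minSupport = 4L,
                                  requireSameDirection = TRUE,
                                  minAvgAbsFC = 1.5) {
  stopifnot(is(panel, "ComparisonPanel"))
  comps <- panel@comparisons
  if (length(comps) == 0L)
    stop("panel contains no comparisons")
  if (minSupport > length(comps))
    stop("minSupport exceeds the number of comparisons")
  gene <- unlist(lapply(comps, geneIds), use.names = FALSE)
  fc <- unlist(lapply(comps, function(b) b@foldChange), use.names = FALSE)
  support <- tapply(fc, gene, length)
  meanFC <- tapply(fc, gene, mean)
  sameDir <- tapply(fc, gene, function(v) all(v > 0) || all(v < 0))
  keep <- support >= minSupport & abs(meanFC) >= minAvgAbsFC
  if (requireSameDirection) keep <- keep & sameDir
  out <- data.frame(gene = names(support)[keep],
                    fold_change = as.numeric(meanFC[keep]),
                    support = as.integer(support[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter candidates for dependence on the knocked-out factor
#'
#' Retains a candidate gene only if its sex difference disappears in the
#' knockout comparisons: in every dependence (knockout male-vs-female)
#' bioset the gene must be absent, or present only with residual
#' |fold-change| below \code{residualFCLimit}. A gene still dimorphic at or
#' above that limit without the factor is removed. An empty dependence list
#' passes every candidate through with a warning (the filter is vacuously
#' satisfied).
#'
#' @param candidates \code{data.frame} from [selectConsistentGenes()]
#'   (columns \code{gene}, \code{fold_change}).
#' @param dependenceComparisons List of knockout [Bioset-class] comparisons.
#' @param residualFCLimit Residual dimorphism tolerated in the knockout
#'   (default 1.2, the compendium upload filter).
#' @return A [BiomarkerGeneSet-class] partitioned into up/down by
#'   fold-change sign.
#' @export
applyDependenceFilter <- function(candidates, dependenceComparisons,
                                  residualFCLimit = 1.2) {
  stopifnot(is.data.frame(candidates),
            all(c("gene", "fold_change") %in% names(candidates)))
  if (length(dependenceComparisons) == 0L) {
    warning("no dependence comparisons supplied; ",
            "dependence filter is vacuously satisfied")
    keep <- rep(TRUE, nrow(candidates))
  } else {
    keep <- rep(TRUE, nrow(candidates))
    for (b in dependenceComparisons) {
      stopifnot(is(b, "Bioset"))
      fc <- foldChanges(b)
      hit <- match(candidates$gene, names(fc))
      persists <- !is.na(hit) & abs(fc[hit]) >= residualFCLimit
      keep <- keep & !persists
    }
  }
  BiomarkerGeneSet(candidates$gene[keep], candidates$fold_change[keep])
}

#' Build a biomarker from a comparison panel
#'
#' Convenience composition of [selectConsistentGenes()] and
#' [applyDependenceFilter()].
#'
#' @inheritParams selectConsistentGenes
#' @inheritParams applyDependenceFilter
#' @return A [BiomarkerGeneSet-class].
#' @export
buildBiomarker <- function(panel, minSupport = 4L,
                           requireSameDirection = TRUE, minAvgAbsFC = 1.5,
                           residualFCLimit = 1.2) {
  cand <- selectConsistentGenes(panel, minSupport, requireSameDirection,
                                minAvgAbsFC)
  applyDependenceFilter(cand, panel@dependenceComparisons, residualFCLimit)
}

#' Residual sex-specific genes shared between two intervention groups
#'
#' Identifies the biomarker genes that retain dimorphic expression after two
#' different hormone-ablating interventions: a gene is reported when it is
#' significantly altered in at least one bioset of \code{groupA} (e.g. the
#' male/female gonadectomized comparisons) AND in \code{biosetB} (e.g. the
#' male/female hypophysectomized comparison), with the same fold-change sign
#' in every bioset where it appears (including between the groupA members
#' themselves). The reported direction is that shared sign.
#'
#' @param groupA List of [Bioset-class] objects.
#' @param biosetB A [Bioset-class].
#' @param biomarker A [BiomarkerGeneSet-class] restricting the gene space.
#' @return \code{data.frame} with columns \code{gene} and \code{direction}
#'   (\code{"up"}/\code{"down"}), with attributes \code{nUp} and
#'   \code{nDown}.
#' @export
residualIntersection <- function(groupA, biosetB, biomarker) {
  stopifnot(is.list(groupA), is(biosetB, "Bioset"),
            is(biomarker, "BiomarkerGeneSet"))
  fcB <- foldChanges(biosetB)
  genes <- character(0); dirs <- character(0)
  for (g in sort(biomarker@gene)) {
    signsA <- vapply(groupA, function(b) {
      fc <- foldChanges(b)
      if (g %in% names(fc)) sign(fc[[g]]) else NA_real_
    }, numeric(1))
    signsA <- signsA[!is.na(signsA)]
    if (length(signsA) == 0L || !g %in% names(fcB)) next
    allSigns <- c(signsA, sign(fcB[[g]]))
    if (length(unique(allSigns)) != 1L) next
    genes <- c(genes, g)
    dirs <- c(dirs, if (allSigns[1L] > 0) "up" else "down")
  }
  out <- data.frame(gene = genes, direction = dirs, stringsAsFactors = FALSE)
  attr(out, "nUp") <- sum(dirs == "up")
  attr(out, "nDown") <- sum(dirs == "down")
  out
}
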
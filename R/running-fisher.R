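# The directional, fold-change rank-based running Fisher similarity test.
#
# A query gene set (one sign half of the biomarker) is compared with a
# ranked target list (one sign half of a bioset, ordered by descending
# |fold-change|). For each rank cut k the 2x2 overlap table against a
# platform universe of n genes is scored with a one-sided Fisher exact
# (hypergeometric upper tail) test; the minimum over the cut grid is
# Bonferroni-corrected by the number of cuts evaluated and capped at 1.
# Four sign quadrants are combined into concordant and discordant evidence
# with Fisher's method, and the smaller combined p-value sets the direction.
# All p-values travel in natural-log space so magnitudes like 1e-27 (and far
# smaller) survive without underflow.

#' One-sided Fisher exact (hypergeometric upper-tail) probability
#'
#' For the 2x2 table \code{[[a, b], [c, d]]} with fixed margins, returns the
#' enrichment probability P(X >= a) where X is hypergeometric with a + b
#' "query" genes drawn among a + c of n = a + b + c + d. This is the
#' elementary statistic scored at every rank cut of the running scan.
#'
#' @param a,b,c,d Non-negative integer cell counts; \code{a} is the overlap.
#'   Vectorized over cells of equal length.
#' @param log.p Return the natural-log probability.
#' @return Upper-tail probability P(X >= a) (or its log).
#' @examples
#' fisherExactOneSided(5, 0, 0, 5)   # 1 / choose(10, 5)
#' fisherExactOneSided(0, 5, 5, 10)  # no overlap: 1
#' @export
fisherExactOneSided <- function(a, b, c, d, log.p = FALSE) {
  if (any(a < 0 | b < 0 | c < 0 | d < 0))
    stop("all cell counts must be non-negative")
  if (any(a + b + c + d == 0))
    stop("the table must contain at least one observation")
  stats::phyper(a - 1, m = a + b, n = c + d, k = a + c,
                lower.tail = FALSE, log.p = log.p)
}

.emptyQuadrant <- function(quadrant) {
  new("QuadrantResult", quadrant = quadrant, bestP = 1, logBestP = 0,
      bestCutRank = 0L, overlapAtBest = 0L, nCutsEvaluated = 0L)
}

#' Default rank-cut grid for the running scan
#'
#' Every rank when the target list has at most \code{denseLimit} genes,
#' otherwise \code{nSparse} evenly spaced ranks (always including the last).
#'
#' @param targetLength Length of the ranked target list.
#' @param denseLimit Maximum length scanned exhaustively (default 500).
#' @param nSparse Number of evenly spaced cuts for longer lists (default
#'   100).
#' @return Strictly increasing integer vector of rank cuts.
#' @export
defaultCutGrid <- function(targetLength, denseLimit = 500L, nSparse = 100L) {
  if (targetLength <= 0L) return(integer(0))
  if (targetLength <= denseLimit) return(seq_len(targetLength))
  unique(as.integer(round(seq(1L, targetLength, length.out = nSparse))))
}

#' Running Fisher scan of a query set along a ranked target list
#'
#' Walks the cut grid over the target ranking. At cut k the table is
#' a = |query intersect top-k|, b = |query| - a, c = k - a,
#' d = n - a - b - c for universe size n; each cut is scored with
#' [fisherExactOneSided()] and the minimum is Bonferroni-corrected by the
#' number of cuts (capped at 1). An empty query or target yields the
#' degenerate result with best p = 1.
#'
#' @param queryGenes Character vector of query gene identifiers.
#' @param targetRanked Character vector: target genes ordered by descending
#'   |fold-change| (see [rankByFoldChange()]).
#' @param universeN Number of genes assayable on the platform; must cover
#'   the union of query and target.
#' @param cutGrid Strictly increasing rank cuts (defaults to
#'   [defaultCutGrid()]).
#' @param quadrant Quadrant label stored in the result.
#' @return A [QuadrantResult-class].
#' @export
runningScan <- function(queryGenes, targetRanked, universeN,
                        cutGrid = NULL, quadrant = "up_up") {
  q <- length(queryGenes)
  tl <- length(targetRanked)
  if (q == 0L || tl == 0L)
    return(.emptyQuadrant(quadrant))
  if (is.null(cutGrid))
    cutGrid <- defaultCutGrid(tl)
  cutGrid <- as.integer(cutGrid)
  if (length(cutGrid) == 0L)
    return(.emptyQuadrant(quadrant))
  if (any(diff(cutGrid) <= 0L) || any(cutGrid < 1L) || any(cutGrid > tl))
    stop("cutGrid must be strictly increasing ranks within the target list")
  nUnion <- length(unique(c(queryGenes, targetRanked)))
  if (universeN < nUnion)
    stop("universeN must be at least the size of the query/target gene union")
  cum <- cumsum(targetRanked %in% queryGenes)
  a <- cum[cutGrid]
  # margins: q query genes among universeN, cutGrid drawn
  logp <- stats::phyper(a - 1, m = q, n = universeN - q, k = cutGrid,
                        lower.tail = FALSE, log.p = TRUE)
  best <- which.min(logp)
  logBest <- min(0, logp[best] + log(length(cutGrid)))
  new("QuadrantResult", quadrant = quadrant, bestP = exp(logBest),
      logBestP = logBest, bestCutRank = cutGrid[best],
      overlapAtBest = as.integer(a[best]),
      nCutsEvaluated = length(cutGrid))
}

# Fisher's method on two quadrant log p-values: -2*sum(ln p) ~ chi^2, 4 df.
.combineQuadrants <- function(logP1, logP2) {
  stats::pchisq(-2 * (logP1 + logP2), df = 4, lower.tail = FALSE,
                log.p = TRUE)
}

#' Directional running Fisher similarity between a biomarker and a bioset
#'
#' Splits the biomarker and the bioset into up- and down-regulated halves
#' (each half ranked by descending |fold-change|) and runs the running
#' Fisher scan on the four sign quadrants. Concordant evidence combines the
#' up_up and down_down quadrants, discordant evidence the up_down and
#' down_up quadrants, each by Fisher's method; the direction is +1
#' (concordant, masculinizing-like) when the concordant combined p is
#' smaller, -1 (anticorrelated, feminizing-like) when larger, 0 on exact
#' ties. The similarity p-value is the smaller combined p. Genes present in
#' the biomarker but absent from the bioset contribute only through the
#' universe margin. The statistic is rank-based: rescaling all bioset
#' fold-change magnitudes by a common factor leaves it unchanged.
#'
#' @param biomarker A [BiomarkerGeneSet-class].
#' @param bioset A nonempty [Bioset-class].
#' @param universeN Platform universe size (default 20000, typical mouse
#'   array coverage); must cover the biomarker/bioset gene union.
#' @param cutGrid Optional explicit cut grid shared by all four scans;
#'   default per-quadrant [defaultCutGrid()].
#' @return A [SimilarityResult-class].
#' @examples
#' bm <- BiomarkerGeneSet(c("A", "B", "C", "D"), c(2, 3, -2, -4))
#' bs <- Bioset("self", c("A", "B", "C", "D"), c(2, 3, -2, -4))
#' res <- directionalSimilarity(bm, bs, universeN = 1000)
#' direction(res)  # +1: concordant
#' @export
directionalSimilarity <- function(biomarker, bioset, universeN = 20000,
                                  cutGrid = NULL) {
  stopifnot(is(biomarker, "BiomarkerGeneSet"), is(bioset, "Bioset"))
  if (length(bioset) == 0L)
    stop("bioset is empty")
  nUnion <- length(unique(c(biomarker@gene, bioset@gene)))
  if (universeN < nUnion)
    stop("universeN must cover the biomarker/bioset gene union")

  bmUp <- upGenes(biomarker)
  bmDown <- downGenes(biomarker)
  up <- bioset@foldChange > 0
  tgtUp <- .rankGenes(bioset@gene[up], bioset@foldChange[up])
  tgtDown <- .rankGenes(bioset@gene[!up], bioset@foldChange[!up])

  quad <- list(
    up_up = runningScan(bmUp, tgtUp, universeN, cutGrid, "up_up"),
    up_down = runningScan(bmUp, tgtDown, universeN, cutGrid, "up_down"),
    down_up = runningScan(bmDown, tgtUp, universeN, cutGrid, "down_up"),
    down_down = runningScan(bmDown, tgtDown, universeN, cutGrid,
                            "down_down"))

  logConc <- .combineQuadrants(quad$up_up@logBestP, quad$down_down@logBestP)
  logDisc <- .combineQuadrants(quad$up_down@logBestP, quad$down_up@logBestP)

  if (logConc < logDisc) {
    dir <- 1L; logP <- logConc
  } else if (logDisc < logConc) {
    dir <- -1L; logP <- logDisc
  } else {
    dir <- 0L; logP <- logConc
  }
  score <- if (dir == 0L || logP == 0) 0 else dir * (-logP / log(10))
  new("SimilarityResult", pValue = exp(logP), logPValue = logP,
      direction = dir, signedScore = score, quadrants = quad,
      overlapGenes = intersect(biomarker@gene, bioset@gene))
}
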
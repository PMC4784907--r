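# Accessor and show methods for the core classes.

#' @rdname accessors
#' @export
setMethod("biosetId", "Bioset", function(x) x@id)

#' @rdname accessors
#' @export
setMethod("geneIds", "Bioset", function(x) x@gene)

#' @rdname accessors
#' @export
setMethod("geneIds", "BiomarkerGeneSet", function(x) x@gene)

#' @rdname accessors
#' @export
setMethod("foldChanges", "Bioset", function(x) {
  stats::setNames(x@foldChange, x@gene)
})

#' @rdname accessors
#' @export
setMethod("foldChanges", "BiomarkerGeneSet", function(x) {
  stats::setNames(x@foldChange, x@gene)
})

#' @rdname accessors
#' @export
setMethod("annotation", "Bioset", function(object, ...) object@annotation)

#' @rdname accessors
#' @export
setMethod("length", "Bioset", function(x) length(x@gene))

#' @rdname accessors
#' @export
setMethod("length", "BiomarkerGeneSet", function(x) length(x@gene))

#' @rdname accessors
#' @export
setMethod("nUp", "BiomarkerGeneSet", function(x) sum(x@foldChange > 0))

#' @rdname accessors
#' @export
setMethod("nDown", "BiomarkerGeneSet", function(x) sum(x@foldChange < 0))

#' @rdname accessors
#' @export
setMethod("upGenes", "BiomarkerGeneSet", function(x) x@gene[x@foldChange > 0])

#' @rdname accessors
#' @export
setMethod("downGenes", "BiomarkerGeneSet",
          function(x) x@gene[x@foldChange < 0])

#' @rdname accessors
#' @export
setMethod("upGenes", "Bioset", function(x) x@gene[x@foldChange > 0])

#' @rdname accessors
#' @export
setMethod("downGenes", "Bioset", function(x) x@gene[x@foldChange < 0])

#' @rdname accessors
#' @export
setMethod("pValue", "SimilarityResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("logPValue", "SimilarityResult", function(x) x@logPValue)

#' @rdname accessors
#' @export
setMethod("direction", "SimilarityResult", function(x) x@direction)

#' @rdname accessors
#' @export
setMethod("quadrants", "SimilarityResult", function(x) x@quadrants)

#' @rdname accessors
#' @export
setMethod("overlapGenes", "SimilarityResult", function(x) x@overlapGenes)

#' @rdname signedLogP
#' @export
setMethod("signedLogP", "SimilarityResult", function(x) {
  x@direction * (-x@logPValue / log(10))
})

#' @describeIn accessors Comparison panel accessors.
#' @export
setGeneric("comparisons", function(x) standardGeneric("comparisons"))

#' @rdname accessors
#' @export
setGeneric("dependenceComparisons",
           function(x) standardGeneric("dependenceComparisons"))

#' @rdname accessors
#' @export
setMethod("comparisons", "ComparisonPanel", function(x) x@comparisons)

#' @rdname accessors
#' @export
setMethod("dependenceComparisons", "ComparisonPanel",
          function(x) x@dependenceComparisons)

setMethod("show", "BiosetAnnotation", function(object) {
  cat("BiosetAnnotation:", object@species, "/", object@tissueSystem,
      "/ sex:", object@sex, "\n")
  cat("  factor:", object@factorCategory,
      if (nzchar(object@factorName)) paste0("(", object@factorName, ")"),
      " accession:", object@accession,
      " in vivo:", object@inVivo, "\n")
})

setMethod("show", "Bioset", function(object) {
  cat(sprintf("Bioset '%s' with %d genes\n", object@id, length(object@gene)))
  cat(sprintf("  up: %d  down: %d\n", sum(object@foldChange > 0),
              sum(object@foldChange < 0)))
  a <- object@annotation
  cat(sprintf("  %s %s, sex %s, factor %s%s\n", a@species, a@tissueSystem,
              a@sex, a@factorCategory,
              if (nzchar(a@factorName)) paste0(" (", a@factorName, ")")
              else ""))
})

setMethod("show", "BiomarkerGeneSet", function(object) {
  cat(sprintf("BiomarkerGeneSet: %d genes (%d up, %d down)\n",
              length(object@gene), sum(object@foldChange > 0),
              sum(object@foldChange < 0)))
  if (length(object@gene)) {
    fc <- abs(object@foldChange)
    cat(sprintf("  |fold-change| range: %.2f - %.2f\n", min(fc), max(fc)))
  }
})

setMethod("show", "ComparisonPanel", function(object) {
  cat(sprintf("ComparisonPanel: %d comparisons, %d dependence comparisons\n",
              length(object@comparisons),
              length(object@dependenceComparisons)))
})

setMethod("show", "QuadrantResult", function(object) {
  cat(sprintf("QuadrantResult [%s]: best p = %.3g at cut %d (overlap %d, %d cuts)\n",
              object@quadrant, object@bestP, object@bestCutRank,
              object@overlapAtBest, object@nCutsEvaluated))
})

setMethod("show", "SimilarityResult", function(object) {
  dirlab <- c("-1" = "anticorrelated (feminizing)",
              "0" = "indeterminate",
              "1" = "concordant (masculinizing)")[as.character(object@direction)]
  cat("SimilarityResult (directional running Fisher test)\n")
  cat(sprintf("  p-value: %.4g  direction: %s\n", object@pValue, dirlab))
  cat(sprintf("  signed -log10(p): %.3f  overlap: %d genes\n",
              signedLogP(object), length(object@overlapGenes)))
})
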
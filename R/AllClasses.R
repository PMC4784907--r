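#' @import methods
NULL

.TISSUE_LEVELS <- c("liver", "primary hepatocytes", "hepatocyte cell line",
                    "other")
.SEX_LEVELS <- c("male", "female", "unspecified")
.CLASS_LEVELS <- c("activated", "suppressed", "unchanged")
.RECEPTOR_LEVELS <- c("activated", "suppressed", "unchanged", "unknown")
.QUADRANTS <- c("up_up", "up_down", "down_up", "down_down")

#' Normalize gene identifiers
#'
#' Gene identity in this package is symbol-based: identifiers are compared
#' after trimming whitespace and case-folding to upper case. Probe-to-gene
#' collapsing is assumed to have happened upstream.
#'
#' @param x Character vector of gene identifiers.
#' @return Normalized character vector.
#' @export
normalizeGene <- function(x) {
  toupper(trimws(as.character(x)))
}

#' BiosetAnnotation: study-level metadata for a bioset
#'
#' Captures the external annotation attached to each comparison: species,
#' tissue system, sex, the category of factor examined (e.g. hormone,
#' chemical, diet, genetic), the specific factor name, the study accession,
#' and whether the experiment was in vivo. Sex may be \code{"unspecified"} —
#' many studies lack a sex designation.
#'
#' @slot species Character scalar, e.g. \code{"mouse"}.
#' @slot tissueSystem One of \code{"liver"}, \code{"primary hepatocytes"},
#'   \code{"hepatocyte cell line"}, \code{"other"}.
#' @slot sex One of \code{"male"}, \code{"female"}, \code{"unspecified"}.
#' @slot factorCategory Character scalar (e.g. \code{"chemical"}).
#' @slot factorName Character scalar (e.g. \code{"phenobarbital"}).
#' @slot accession Character scalar study accession (e.g. a GEO series id).
#' @slot inVivo Logical scalar.
#' @export
setClass("BiosetAnnotation",
  representation(species = "character", tissueSystem = "character",
                 sex = "character", factorCategory = "character",
                 factorName = "character", accession = "character",
                 inVivo = "logical"),
  prototype(species = "mouse", tissueSystem = "liver", sex = "unspecified",
            factorCategory = "", factorName = "", accession = "",
            inVivo = TRUE))

setValidity("BiosetAnnotation", function(object) {
  msg <- character(0)
  for (sl in c("species", "tissueSystem", "sex", "factorCategory",
               "factorName", "accession"))
    if (length(slot(object, sl)) != 1L)
      msg <- c(msg, sprintf("'%s' must be a character scalar", sl))
  if (length(object@tissueSystem) == 1L &&
      !object@tissueSystem %in% .TISSUE_LEVELS)
    msg <- c(msg, sprintf("tissueSystem must be one of: %s",
                          paste(.TISSUE_LEVELS, collapse = ", ")))
  if (length(object@sex) == 1L && !object@sex %in% .SEX_LEVELS)
    msg <- c(msg, sprintf("sex must be one of: %s",
                          paste(.SEX_LEVELS, collapse = ", ")))
  if (length(object@inVivo) != 1L || is.na(object@inVivo))
    msg <- c(msg, "inVivo must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a BiosetAnnotation
#'
#' @param species,tissueSystem,sex,factorCategory,factorName,accession,inVivo
#'   See the class slots of [BiosetAnnotation-class].
#' @return A \code{BiosetAnnotation} object.
#' @examples
#' BiosetAnnotation(species = "mouse", sex = "male",
#'                  factorCategory = "chemical", factorName = "phenobarbital")
#' @export
BiosetAnnotation <- function(species = "mouse", tissueSystem = "liver",
                             sex = "unspecified", factorCategory = "",
                             factorName = "", accession = "",
                             inVivo = TRUE) {
  new("BiosetAnnotation", species = species, tissueSystem = tissueSystem,
      sex = sex, factorCategory = factorCategory, factorName = factorName,
      accession = accession, inVivo = inVivo)
}

#' Bioset: a statistically filtered gene list with signed fold-changes
#'
#' The universal unit of comparison: a set of differentially expressed genes
#' from one two-condition comparison, each carrying a signed linear
#' fold-change. The linear signed convention is used throughout: a 20%
#' increase is +1.2 and a 20% decrease is -1.2, so every magnitude is >= 1
#' and 0 is impossible. Genes are unique within a bioset.
#'
#' @slot id Character scalar bioset identifier.
#' @slot gene Character vector of normalized gene symbols (unique).
#' @slot foldChange Numeric vector of signed linear fold-changes, parallel
#'   to \code{gene}.
#' @slot annotation A [BiosetAnnotation-class].
#' @export
setClass("Bioset",
  representation(id = "character", gene = "character",
                 foldChange = "numeric", annotation = "BiosetAnnotation"),
  prototype(id = "", gene = character(0), foldChange = numeric(0)))

setValidity("Bioset", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L)
    msg <- c(msg, "id must be a character scalar")
  if (length(object@gene) != length(object@foldChange))
    msg <- c(msg, "gene and foldChange must have equal length")
  if (anyDuplicated(object@gene))
    msg <- c(msg, sprintf("duplicate gene(s): %s",
      paste(unique(object@gene[duplicated(object@gene)]), collapse = ", ")))
  if (any(!nzchar(object@gene)))
    msg <- c(msg, "gene identifiers must be non-empty")
  fc <- object@foldChange
  if (length(fc) && (any(!is.finite(fc)) || any(abs(fc) < 1)))
    msg <- c(msg, paste0("fold-changes must be finite signed linear ratios ",
                         "with |fold-change| >= 1"))
  if (length(msg)) msg else TRUE
})

#' Construct a Bioset
#'
#' @param id Bioset identifier.
#' @param gene Character vector of gene identifiers (normalized on entry).
#' @param foldChange Numeric vector of signed linear fold-changes
#'   (|fc| >= 1, never 0).
#' @param annotation A [BiosetAnnotation-class]; defaults to an unannotated
#'   mouse liver study.
#' @return A \code{Bioset}.
#' @examples
#' Bioset("bs1", gene = c("Cyp2b9", "Mup1"), foldChange = c(-3.0, 5.2))
#' @export
Bioset <- function(id, gene = character(0), foldChange = numeric(0),
                   annotation = BiosetAnnotation()) {
  new("Bioset", id = as.character(id), gene = normalizeGene(gene),
      foldChange = as.numeric(foldChange), annotation = annotation)
}

#' BiomarkerGeneSet: a directional gene expression signature
#'
#' A curated signature whose coordinated up/down pattern reports on a
#' transcription factor's functional status. Each gene carries an average
#' signed fold-change across the source comparisons; every magnitude is
#' >= 1.5 and the up/down partition follows the fold-change signs exactly.
#'
#' @slot gene Character vector of normalized gene symbols (unique).
#' @slot foldChange Numeric vector of signed average fold-changes, parallel
#'   to \code{gene}, all with |fc| >= 1.5.
#' @export
setClass("BiomarkerGeneSet",
  representation(gene = "character", foldChange = "numeric"),
  prototype(gene = character(0), foldChange = numeric(0)))

setValidity("BiomarkerGeneSet", function(object) {
  msg <- character(0)
  if (length(object@gene) != length(object@foldChange))
    msg <- c(msg, "gene and foldChange must have equal length")
  if (anyDuplicated(object@gene))
    msg <- c(msg, "duplicate genes in biomarker")
  if (any(!nzchar(object@gene)))
    msg <- c(msg, "gene identifiers must be non-empty")
  fc <- object@foldChange
  if (length(fc) && (any(!is.finite(fc)) || any(abs(fc) < 1.5)))
    msg <- c(msg, "biomarker fold-changes must satisfy |fold-change| >= 1.5")
  if (length(msg)) msg else TRUE
})

#' Construct a BiomarkerGeneSet
#'
#' @param gene Character vector of gene identifiers (normalized on entry).
#' @param foldChange Signed average fold-changes, |fc| >= 1.5.
#' @return A \code{BiomarkerGeneSet}.
#' @export
BiomarkerGeneSet <- function(gene, foldChange) {
  new("BiomarkerGeneSet", gene = normalizeGene(gene),
      foldChange = as.numeric(foldChange))
}

#' ComparisonPanel: replicate dimorphism comparisons plus dependence checks
#'
#' Holds the male-versus-female liver comparisons from which a dimorphic
#' biomarker is derived, together with the corresponding comparisons in
#' knockout animals used to test whether each candidate gene's dimorphism
#' depends on the factor of interest.
#'
#' @slot comparisons List of [Bioset-class] objects (significance-filtered
#'   male-vs-female comparisons); must be nonempty.
#' @slot dependenceComparisons List of [Bioset-class] objects (the same
#'   comparison in knockout animals); may be empty.
#' @export
setClass("ComparisonPanel",
  representation(comparisons = "list", dependenceComparisons = "list"))

setValidity("ComparisonPanel", function(object) {
  msg <- character(0)
  if (length(object@comparisons) == 0L)
    msg <- c(msg, "comparisons must be a nonempty list of Bioset objects")
  if (!all(vapply(object@comparisons, is, logical(1), class2 = "Bioset")))
    msg <- c(msg, "all comparisons must be Bioset objects")
  if (!all(vapply(object@dependenceComparisons, is, logical(1),
                  class2 = "Bioset")))
    msg <- c(msg, "all dependenceComparisons must be Bioset objects")
  if (length(msg)) msg else TRUE
})

#' Construct a ComparisonPanel
#'
#' @param comparisons Nonempty list of [Bioset-class] male-vs-female
#'   comparisons.
#' @param dependenceComparisons List of knockout male-vs-female
#'   [Bioset-class] comparisons (may be empty).
#' @return A \code{ComparisonPanel}.
#' @export
ComparisonPanel <- function(comparisons, dependenceComparisons = list()) {
  new("ComparisonPanel", comparisons = comparisons,
      dependenceComparisons = dependenceComparisons)
}

#' QuadrantResult: the running Fisher scan over one sign quadrant
#'
#' One directional similarity computation decomposes into four quadrant
#' scans (biomarker up/down half against bioset up/down half). Each scan
#' records the best multiplicity-corrected tail probability over the cut
#' grid, the rank cut achieving it, the overlap there, and the number of
#' cuts evaluated. The log-scale p-value is retained so that magnitudes
#' far below double-precision underflow of products survive downstream
#' combination.
#'
#' @slot quadrant One of \code{"up_up"}, \code{"up_down"}, \code{"down_up"},
#'   \code{"down_down"}.
#' @slot bestP Best corrected p-value in (0, 1].
#' @slot logBestP Natural-log of \code{bestP}.
#' @slot bestCutRank Rank cut achieving the best p (0 for degenerate scans).
#' @slot overlapAtBest Overlap count at the best cut.
#' @slot nCutsEvaluated Number of rank cuts scanned.
#' @export
setClass("QuadrantResult",
  representation(quadrant = "character", bestP = "numeric",
                 logBestP = "numeric", bestCutRank = "integer",
                 overlapAtBest = "integer", nCutsEvaluated = "integer"))

setValidity("QuadrantResult", function(object) {
  msg <- character(0)
  if (!object@quadrant %in% .QUADRANTS)
    msg <- c(msg, "unknown quadrant label")
  if (object@bestP > 1 || object@bestP < 0 ||
      (object@bestP == 0 && object@logBestP > log(.Machine$double.xmin)))
    msg <- c(msg, "bestP must lie in (0, 1] (0 only on linear underflow)")
  if (object@logBestP > 0)
    msg <- c(msg, "logBestP must be <= 0")
  if (object@overlapAtBest < 0L ||
      (object@bestCutRank > 0L && object@overlapAtBest > object@bestCutRank))
    msg <- c(msg, "overlapAtBest must lie in [0, bestCutRank]")
  if (length(msg)) msg else TRUE
})

#' SimilarityResult: output of the directional running Fisher test
#'
#' @slot pValue Similarity p-value in (0, 1] (the smaller of the concordant
#'   and discordant combined quadrant p-values).
#' @slot logPValue Natural-log p-value (exact even when \code{pValue}
#'   underflows display precision).
#' @slot direction +1 for concordant (masculinizing-like) correlation, -1
#'   for anticorrelated (feminizing-like), 0 for indeterminate ties.
#' @slot signedScore \code{direction * -log10(pValue)}, the master-table
#'   score.
#' @slot quadrants Named list of four [QuadrantResult-class] objects.
#' @slot overlapGenes Genes shared between biomarker and bioset.
#' @export
setClass("SimilarityResult",
  representation(pValue = "numeric", logPValue = "numeric",
                 direction = "integer", signedScore = "numeric",
                 quadrants = "list", overlapGenes = "character"))

setValidity("SimilarityResult", function(object) {
  msg <- character(0)
  if (object@pValue > 1 || object@pValue < 0 ||
      (object@pValue == 0 && object@logPValue > log(.Machine$double.xmin)))
    msg <- c(msg, "pValue must lie in (0, 1] (0 only on linear underflow)")
  if (!object@direction %in% c(-1L, 0L, 1L))
    msg <- c(msg, "direction must be -1, 0 or +1")
  if (!identical(sort(names(object@quadrants)), sort(.QUADRANTS)))
    msg <- c(msg, "quadrants must be named up_up, up_down, down_up, down_down")
  if ((object@direction == 0L || object@logPValue == 0) &&
      object@signedScore != 0)
    msg <- c(msg, "signedScore must be 0 when direction is 0 or p = 1")
  if (length(msg)) msg else TRUE
})
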
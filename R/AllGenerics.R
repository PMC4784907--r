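#' @title Accessor generics
#' @description Accessors for the core classes. Slot access from user code
#'   should always go through these.
#' @param x,object An object of one of the package classes.
#' @param ... Further arguments passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("biosetId", function(x) standardGeneric("biosetId"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' @rdname accessors
#' @export
setGeneric("annotation", function(object, ...) standardGeneric("annotation"))

#' @rdname accessors
#' @export
setGeneric("nUp", function(x) standardGeneric("nUp"))

#' @rdname accessors
#' @export
setGeneric("nDown", function(x) standardGeneric("nDown"))

#' @rdname accessors
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @rdname accessors
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("logPValue", function(x) standardGeneric("logPValue"))

#' @rdname accessors
#' @export
setGeneric("direction", function(x) standardGeneric("direction"))

#' @rdname accessors
#' @export
setGeneric("quadrants", function(x) standardGeneric("quadrants"))

#' @rdname accessors
#' @export
setGeneric("overlapGenes", function(x) standardGeneric("overlapGenes"))

#' Signed -log10 similarity score
#'
#' Converts a similarity result to the master-table score: -log10 of the
#' similarity p-value, negated for anticorrelated (feminizing) biosets and 0
#' for indeterminate direction or p = 1. Computed from the log-scale
#' p-value, so scores like 27 (p = 1e-27) are exact.
#'
#' @param x A [SimilarityResult-class].
#' @return Numeric scalar, \code{direction * -log10(pValue)}.
#' @export
setGeneric("signedLogP", function(x) standardGeneric("signedLogP"))
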
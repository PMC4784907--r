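# Reading, writing and basic filtering of bioset TSV files.
#
# File format: UTF-8 tab-separated text with two columns, gene and signed
# linear fold-change. Lines starting with '#' carry key=value annotation
# (e.g. "#sex=male", "#factor_name=phenobarbital"); keys mirror the
# BiosetAnnotation fields. An optional "gene<TAB>fold_change" header line is
# tolerated.

.ANNOTATION_KEYS <- c(species = "species", tissue_system = "tissueSystem",
                      sex = "sex", factor_category = "factorCategory",
                      factor_name = "factorName", accession = "accession",
                      in_vivo = "inVivo")

.parseAnnotationLines <- function(lines) {
  ann <- BiosetAnnotation()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (!grepl("=", body, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", body))
    val <- trimws(sub("^[^=]*=", "", body))
    if (!key %in% names(.ANNOTATION_KEYS)) next
    slotName <- .ANNOTATION_KEYS[[key]]
    if (slotName == "inVivo") {
      slot(ann, slotName) <- toupper(val) %in% c("TRUE", "YES", "1")
    } else {
      slot(ann, slotName) <- val
    }
  }
  validObject(ann)
  ann
}

#' Read a bioset from a two-column TSV file
#'
#' Parses a gene/fold-change table into a [Bioset-class]. Comment lines
#' (\code{#key=value}) are read into the annotation unless an explicit
#' \code{annotation} is supplied. Gene symbols are whitespace- and
#' case-normalized; duplicate genes and zero or unparsable fold-changes are
#' errors (the duplicate-gene error names the gene; parse errors report the
#' line number). An empty file yields a valid empty bioset.
#'
#' @param path Path to a TSV file with columns \code{gene} and
#'   \code{fold_change}.
#' @param annotation Optional [BiosetAnnotation-class] overriding any
#'   annotation found in the file header.
#' @param id Bioset identifier; defaults to the file name without extension.
#' @return A [Bioset-class].
#' @seealso [writeBioset()], [filterFoldChange()]
#' @export
readBioset <- function(path, annotation = NULL, id = NULL) {
  if (!file.exists(path))
    stop("bioset file not found: ", path)
  if (is.null(id))
    id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  isComment <- startsWith(lines, "#")
  if (is.null(annotation))
    annotation <- .parseAnnotationLines(lines[isComment])
  dataIdx <- which(!isComment & nzchar(trimws(lines)))
  # tolerate a single header line
  if (length(dataIdx)) {
    first <- strsplit(lines[dataIdx[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(first) >= 2L && is.na(suppressWarnings(as.numeric(first[2L]))))
      dataIdx <- dataIdx[-1L]
  }
  genes <- character(length(dataIdx))
  fcs <- numeric(length(dataIdx))
  for (i in seq_along(dataIdx)) {
    lineNo <- dataIdx[i]
    fields <- strsplit(lines[lineNo], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 2L)
      stop(sprintf("line %d of '%s': expected 2 tab-separated columns",
                   lineNo, path))
    fc <- suppressWarnings(as.numeric(fields[2L]))
    if (is.na(fc))
      stop(sprintf("line %d of '%s': unparsable fold-change '%s'",
                   lineNo, path, fields[2L]))
    if (fc == 0)
      stop(sprintf("line %d of '%s': fold-change of 0 is not a valid signed linear ratio",
                   lineNo, path))
    genes[i] <- normalizeGene(fields[1L])
    fcs[i] <- fc
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene(s) in '", path, "': ", paste(dup, collapse = ", "))
  Bioset(id = id, gene = genes, foldChange = fcs, annotation = annotation)
}

#' Write a bioset to TSV
#'
#' Writes the annotation as \code{#key=value} comment lines followed by a
#' \code{gene<TAB>fold_change} table. [readBioset()] round-trips the result.
#'
#' @param bioset A [Bioset-class].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeBioset <- function(bioset, path) {
  stopifnot(is(bioset, "Bioset"))
  a <- bioset@annotation
  vals <- c(species = a@species, tissue_system = a@tissueSystem, sex = a@sex,
            factor_category = a@factorCategory, factor_name = a@factorName,
            accession = a@accession,
            in_vivo = tolower(as.character(a@inVivo)))
  header <- sprintf("#%s=%s", names(vals), vals)
  body <- c("gene\tfold_change",
            sprintf("%s\t%.6g", bioset@gene, bioset@foldChange))
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}

#' Filter a bioset by absolute fold-change
#'
#' Keeps exactly the entries with |fold-change| >= \code{minAbsFC}
#' (inclusive). The default 1.2 is the compendium upload filter applied to
#' every statistically filtered gene list before comparison. Annotation and
#' id are preserved; the operation is idempotent and monotone in the
#' threshold.
#'
#' @param bioset A [Bioset-class].
#' @param minAbsFC Minimum absolute linear fold-change, >= 1.
#' @return The filtered [Bioset-class].
#' @export
filterFoldChange <- function(bioset, minAbsFC = 1.2) {
  stopifnot(is(bioset, "Bioset"), length(minAbsFC) == 1L, minAbsFC >= 1)
  keep <- abs(bioset@foldChange) >= minAbsFC
  new("Bioset", id = bioset@id, gene = bioset@gene[keep],
      foldChange = bioset@foldChange[keep], annotation = bioset@annotation)
}

# Deterministic ranking shared by the scan: descending |fc|, ties broken
# lexicographically by gene id.
.rankGenes <- function(gene, foldChange) {
  gene[order(-abs(foldChange), gene, method = "radix")]
}

#' Rank bioset genes by fold-change magnitude
#'
#' Returns the gene identifiers sorted by descending absolute fold-change,
#' with ties broken lexicographically so the ranking is deterministic. This
#' is the ordering the running Fisher scan consumes.
#'
#' @param bioset A nonempty [Bioset-class].
#' @return Character vector: a permutation of the bioset's genes.
#' @export
rankByFoldChange <- function(bioset) {
  stopifnot(is(bioset, "Bioset"))
  if (length(bioset@gene) == 0L)
    stop("cannot rank an empty bioset")
  .rankGenes(bioset@gene, bioset@foldChange)
}
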
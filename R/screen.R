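# Compendium-level screening: the annotated master table and its summaries.

.MASTER_COLS <- c("bioset_id", "species", "tissue", "sex", "factor_category",
                  "factor_name", "accession", "p_value", "direction",
                  "signed_score", "stat5b_call", "ahr_call", "car_call",
                  "pparalpha_call")

#' Screen a list of biosets against a biomarker into a master table
#'
#' Runs [directionalSimilarity()] and [classifyStatus()] for every bioset
#' and assembles one row per bioset with its annotations, similarity
#' p-value, correlation direction, signed -log10(p) score, classification
#' call, and (optionally) externally supplied receptor-activation calls for
#' AhR, CAR and PPARalpha. Receptor predictions are consumed as given,
#' never recomputed; rows without predictions carry \code{"unknown"}.
#' When \code{restrictMouseLiver} is set, only mouse biosets from liver,
#' primary hepatocytes or hepatocyte cell lines are evaluated.
#'
#' @param biomarker A [BiomarkerGeneSet-class].
#' @param biosets List of [Bioset-class] objects with unique ids.
#' @param universeN Platform universe size (default 20000).
#' @param receptorPredictions Optional \code{data.frame} with columns
#'   \code{bioset_id}, \code{ahr_call}, \code{car_call},
#'   \code{pparalpha_call}; unknown bioset ids are ignored with a warning.
#' @param cutoff Classification p-value cutoff (default 1e-4).
#' @param restrictMouseLiver Apply the mouse liver / hepatocyte tissue
#'   filter (default FALSE).
#' @return \code{data.frame} with the fixed master-table column order.
#' @export
buildMasterTable <- function(biomarker, biosets, universeN = 20000,
                             receptorPredictions = NULL, cutoff = 1e-4,
                             restrictMouseLiver = FALSE) {
  stopifnot(is(biomarker, "BiomarkerGeneSet"), is.list(biosets))
  ids <- vapply(biosets, biosetId, character(1))
  if (anyDuplicated(ids))
    stop("bioset ids must be unique; duplicated: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (restrictMouseLiver) {
    keep <- vapply(biosets, function(b) {
      a <- b@annotation
      a@species == "mouse" && a@tissueSystem %in%
        c("liver", "primary hepatocytes", "hepatocyte cell line")
    }, logical(1))
    biosets <- biosets[keep]
    ids <- ids[keep]
  }
  n <- length(biosets)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    b <- biosets[[i]]
    a <- b@annotation
    res <- directionalSimilarity(biomarker, b, universeN)
    rows[[i]] <- data.frame(
      bioset_id = b@id, species = a@species, tissue = a@tissueSystem,
      sex = a@sex, factor_category = a@factorCategory,
      factor_name = a@factorName, accession = a@accession,
      p_value = res@pValue, direction = res@direction,
      signed_score = signedLogP(res),
      stat5b_call = as.character(classifyStatus(res, cutoff)),
      ahr_call = "unknown", car_call = "unknown",
      pparalpha_call = "unknown", stringsAsFactors = FALSE)
  }
  master <- if (n) do.call(rbind, rows) else
    stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(.MASTER_COLS))),
                    .MASTER_COLS)
  if (!is.null(receptorPredictions) && nrow(master)) {
    rp <- receptorPredictions
    stopifnot(is.data.frame(rp), "bioset_id" %in% names(rp))
    unknown <- setdiff(rp$bioset_id, master$bioset_id)
    if (length(unknown))
      warning("receptor predictions for unknown bioset ids ignored: ",
              paste(unknown, collapse = ", "))
    hit <- match(master$bioset_id, rp$bioset_id)
    for (col in c("ahr_call", "car_call", "pparalpha_call")) {
      if (!col %in% names(rp)) next
      val <- as.character(rp[[col]][hit])
      ok <- !is.na(hit) & !is.na(val) & val %in% .RECEPTOR_LEVELS
      master[[col]][ok] <- val[ok]
    }
  }
  master[, .MASTER_COLS]
}

#' Fractions of masculinized and feminized biosets per annotation group
#'
#' Counts, per group of master-table rows, the biosets called activated
#' (masculinized) and suppressed (feminized), with percentages rounded to
#' the nearest integer. Percentages are always recomputed from the counts
#' in the same row, so they never drift from them. Empty input yields an
#' empty summary; a group of size 0 cannot arise from grouping, but an
#' all-unchanged group reports 0%.
#'
#' @param master Master table from [buildMasterTable()].
#' @param groupBy Character vector of master-table annotation columns to
#'   group by (default \code{"sex"}).
#' @return \code{data.frame} with the grouping columns plus
#'   \code{n_total}, \code{n_masculinized}, \code{n_feminized},
#'   \code{pct_masculinized}, \code{pct_feminized}.
#' @export
summarizeFractions <- function(master, groupBy = "sex") {
  stopifnot(is.data.frame(master), "stat5b_call" %in% names(master),
            all(groupBy %in% names(master)))
  if (nrow(master) == 0L) {
    out <- master[, groupBy, drop = FALSE]
    out$n_total <- integer(0); out$n_masculinized <- integer(0)
    out$n_feminized <- integer(0); out$pct_masculinized <- numeric(0)
    out$pct_feminized <- numeric(0)
    return(out)
  }
  key <- interaction(master[groupBy], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(master)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    g <- master[i[1L], groupBy, drop = FALSE]
    nm <- sum(master$stat5b_call[i] == "activated")
    nf <- sum(master$stat5b_call[i] == "suppressed")
    cbind(g, data.frame(n_total = length(i), n_masculinized = nm,
                        n_feminized = nf,
                        pct_masculinized = round(100 * nm / length(i)),
                        pct_feminized = round(100 * nf / length(i))))
  }))
  rownames(out) <- NULL
  out
}

#' Cross-tabulate classification calls with receptor-activation calls
#'
#' Produces (i) contingency tables of the biomarker classification against
#' each receptor call, (ii) the count and percentage of feminized
#' (suppressed) rows in which at least one of AhR, CAR or PPARalpha is
#' activated, and (iii) the seven-region Venn partition of those feminized
#' rows over the three receptors. The Venn regions are disjoint and sum to
#' the count of feminized rows with at least one activation.
#'
#' @param master Master table with receptor calls populated for the rows
#'   considered; an error is raised if every receptor call is unknown.
#' @return List with elements \code{crosstabs} (list of three tables),
#'   \code{nFeminized}, \code{nFeminizedWithActivation},
#'   \code{pctFeminizedWithActivation} (nearest integer) and \code{venn}
#'   (named integer vector over the 7 regions).
#' @export
coModulationCrosstab <- function(master) {
  stopifnot(is.data.frame(master),
            all(c("stat5b_call", "ahr_call", "car_call", "pparalpha_call")
                %in% names(master)))
  rec <- master[, c("ahr_call", "car_call", "pparalpha_call")]
  if (nrow(master) == 0L || all(unlist(rec) == "unknown"))
    stop("all receptor calls are unknown; supply receptor predictions ",
         "(buildMasterTable(receptorPredictions = ...))")
  crosstabs <- lapply(c(AhR = "ahr_call", CAR = "car_call",
                        PPARalpha = "pparalpha_call"), function(col)
    table(stat5b = factor(master$stat5b_call, levels = .CLASS_LEVELS),
          receptor = factor(master[[col]], levels = .RECEPTOR_LEVELS)))
  fem <- master$stat5b_call == "suppressed"
  A <- fem & master$ahr_call == "activated"
  C <- fem & master$car_call == "activated"
  P <- fem & master$pparalpha_call == "activated"
  anyAct <- A | C | P
  venn <- c(
    "AhR" = sum(A & !C & !P), "CAR" = sum(!A & C & !P),
    "PPARalpha" = sum(!A & !C & P), "AhR&CAR" = sum(A & C & !P),
    "AhR&PPARalpha" = sum(A & !C & P), "CAR&PPARalpha" = sum(!A & C & P),
    "AhR&CAR&PPARalpha" = sum(A & C & P))
  nFem <- sum(fem)
  nAct <- sum(anyAct)
  list(crosstabs = crosstabs, nFeminized = nFem,
       nFeminizedWithActivation = nAct,
       pctFeminizedWithActivation = if (nFem) round(100 * nAct / nFem) else 0,
       venn = venn)
}

#' Fold-change matrix of biomarker genes across biosets
#'
#' Builds the genes-by-biosets matrix underlying the rank-ordered biomarker
#' heatmaps: rows are the biomarker genes ordered by descending biomarker
#' fold-change (up-regulated block first), columns follow the input bioset
#' order, and a cell holds the bioset's fold-change for that gene or NA
#' when the gene is absent. On export the sentinel is an empty cell, never
#' 0, because 0 may equally mean "not measured".
#'
#' @param biomarker A [BiomarkerGeneSet-class].
#' @param biosets List of [Bioset-class] objects.
#' @return Numeric matrix, rownames = biomarker genes, colnames = bioset
#'   ids, NA = gene absent from the bioset.
#' @export
heatmapMatrix <- function(biomarker, biosets) {
  stopifnot(is(biomarker, "BiomarkerGeneSet"), is.list(biosets))
  ord <- order(-biomarker@foldChange, biomarker@gene, method = "radix")
  genes <- biomarker@gene[ord]
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(biosets),
              dimnames = list(genes,
                              vapply(biosets, biosetId, character(1))))
  for (j in seq_along(biosets)) {
    fc <- foldChanges(biosets[[j]])
    hit <- match(genes, names(fc))
    m[!is.na(hit), j] <- fc[hit[!is.na(hit)]]
  }
  m
}

#' Write a heatmap matrix as TSV with empty cells for missing values
#'
#' @param m Matrix from [heatmapMatrix()].
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeHeatmapMatrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}
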
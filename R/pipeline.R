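# End-to-end screening pipeline over bioset files on disk.

.writeAtomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

.writeTSV <- function(df, path) {
  .writeAtomic(function(tmp)
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = ""), path)
}

#' Run the full compendium screen over bioset files
#'
#' Reads a biomarker file (Bioset-format TSV with signed average
#' fold-changes) and a directory of bioset TSVs, applies the upload filter,
#' computes the directional running Fisher similarity for every bioset,
#' classifies each as masculinized/feminized/unchanged, and writes the
#' master table, the per-group fraction summary, optionally the receptor
#' co-modulation Venn partition (when receptor predictions are supplied)
#' and single-gene enrichment tables, plus a run log echoing every
#' configuration value. All inputs are read and validated before the first
#' output file is written, and each table is written atomically
#' (write-then-rename), so a failed run leaves no partial outputs.
#'
#' @param biomarkerFile Path to the biomarker TSV (entries must satisfy
#'   |fold-change| >= 1.5).
#' @param biosetDir Directory of bioset \code{.tsv} files.
#' @param outDir Output directory (created if needed).
#' @param receptorFile Optional TSV with columns \code{bioset_id},
#'   \code{ahr_call}, \code{car_call}, \code{pparalpha_call}.
#' @param enrichGenes Optional character vector of genes for the
#'   enrichment report (e.g. \code{"Pparg"}).
#' @param cutoff Classification p-value cutoff (default 1e-4).
#' @param universeN Platform universe size (default 20000).
#' @param uploadFilter Absolute fold-change upload filter (default 1.2).
#' @param fcGeneThreshold Single-gene altered-expression threshold for the
#'   enrichment report (default 1.5).
#' @param bhAlpha FDR level echoed for [bhCutoff()] re-derivation (default
#'   0.001).
#' @param groupBy Grouping columns for the fraction summary (default
#'   \code{"sex"}).
#' @return Invisibly, the master table.
#' @export
runScreenPipeline <- function(biomarkerFile, biosetDir, outDir,
                              receptorFile = NULL, enrichGenes = NULL,
                              cutoff = 1e-4, universeN = 20000,
                              uploadFilter = 1.2, fcGeneThreshold = 1.5,
                              bhAlpha = 0.001, groupBy = "sex") {
  if (!file.exists(biomarkerFile))
    stop("biomarker file not found: ", biomarkerFile)
  if (!dir.exists(biosetDir))
    stop("bioset directory not found: ", biosetDir)
  bmRaw <- readBioset(biomarkerFile, id = "biomarker")
  biomarker <- BiomarkerGeneSet(bmRaw@gene, bmRaw@foldChange)
  files <- sort(list.files(biosetDir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0L)
    stop("no .tsv bioset files in ", biosetDir)
  biosets <- lapply(files, function(f)
    filterFoldChange(readBioset(f), uploadFilter))
  receptors <- if (!is.null(receptorFile))
    utils::read.delim(receptorFile, stringsAsFactors = FALSE) else NULL

  master <- buildMasterTable(biomarker, biosets, universeN = universeN,
                             receptorPredictions = receptors,
                             cutoff = cutoff)
  fractions <- summarizeFractions(master, groupBy = groupBy)

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  .writeTSV(master, file.path(outDir, "master.tsv"))
  .writeTSV(fractions, file.path(outDir, "fractions.tsv"))
  if (!is.null(receptors)) {
    cm <- coModulationCrosstab(master)
    venn <- data.frame(region = names(cm$venn),
                       n_feminized = as.integer(cm$venn))
    .writeTSV(venn, file.path(outDir, "venn.tsv"))
  }
  if (!is.null(enrichGenes)) {
    enr <- do.call(rbind, lapply(enrichGenes, function(g) {
      counts <- geneChangeByStatus(g, master, biosets, fcGeneThreshold)
      res <- lapply(c("activated", "suppressed"), function(st) {
        row <- counts[counts$status == st, ]
        ok <- row$n_increased + row$n_decreased > 0 &&
          sum(counts[counts$status == "unchanged",
                     c("n_increased", "n_decreased")]) > 0
        et <- if (ok) enrichmentTest(counts, st) else
          list(p.value = NA_real_, stars = "")
        data.frame(gene = normalizeGene(g), status = st,
                   n_increased = row$n_increased,
                   n_decreased = row$n_decreased,
                   p_value = et$p.value, stars = et$stars,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    }))
    .writeTSV(enr, file.path(outDir, "enrichment.tsv"))
  }
  logLines <- c(
    sprintf("dimorphScan %s run %s",
            as.character(utils::packageVersion("dimorphScan")),
            format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("R %s", as.character(getRversion())),
    sprintf("biomarker_file=%s", biomarkerFile),
    sprintf("bioset_dir=%s (%d biosets)", biosetDir, length(biosets)),
    sprintf("receptor_file=%s",
            if (is.null(receptorFile)) "none" else receptorFile),
    sprintf("cutoff=%g", cutoff),
    sprintf("universe_n=%d", as.integer(universeN)),
    sprintf("fc_upload_filter=%g", uploadFilter),
    sprintf("fc_gene_threshold=%g", fcGeneThreshold),
    sprintf("bh_alpha=%g", bhAlpha),
    sprintf("group_by=%s", paste(groupBy, collapse = ",")))
  .writeAtomic(function(tmp) writeLines(logLines, tmp),
               file.path(outDir, "run.log"))
  invisible(master)
}
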
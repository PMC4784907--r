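# Synthetic bioset generator: planted dimorphic signature, graded
# concordant/anti-concordant treatment effects, nulls, platform dropout and
# background noise — with ground-truth labels for end-to-end validation.

#' Configuration of the synthetic bioset generator
#'
#' Returns the generator settings as a validated list. Defaults emulate the
#' screening conditions: a planted signature of 74 up- and 70 down-regulated
#' genes whose |fold-change| follows a log-normal law floored at 1.5 (the
#' biomarker magnitude rule), 400 background noise genes per bioset with
#' |fold-change| log-uniform on \[1.2, 3\] (so the 1.2 upload filter is
#' observable but not vacuous), a per-gene detection probability rising
#' logistically from 0.05 at no effect to 0.95 at full effect, multiplicative
#' jitter of sd 0.15 on the log fold-change, and a 20000-gene platform
#' universe.
#'
#' @param nUpTruth,nDownTruth Planted signature sizes (default 74 and 70).
#' @param signatureFCMeanlog,signatureFCSdlog Log-normal parameters of the
#'   signature |fold-change| law.
#' @param signatureFCFloor Lower bound on signature |fold-change| (1.5).
#' @param nBackgroundGenes Background noise genes per bioset (400).
#' @param backgroundFCRange |fold-change| range of background genes, drawn
#'   log-uniformly (c(1.2, 3)).
#' @param detectProbNull,detectProbFull Signature-gene inclusion probability
#'   at |effect| = 0 and |effect| = 1 (0.05 and 0.95); intermediate effects
#'   interpolate logistically.
#' @param noiseSd Standard deviation of Gaussian jitter added to the log
#'   fold-change (0.15).
#' @param uploadFilter Absolute fold-change filter applied to every
#'   generated bioset (1.2).
#' @param universeN Platform universe size (20000).
#' @return A list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(nUpTruth = 74L, nDownTruth = 70L,
                            signatureFCMeanlog = log(2.5),
                            signatureFCSdlog = 0.6,
                            signatureFCFloor = 1.5,
                            nBackgroundGenes = 400L,
                            backgroundFCRange = c(1.2, 3),
                            detectProbNull = 0.05, detectProbFull = 0.95,
                            noiseSd = 0.15, uploadFilter = 1.2,
                            universeN = 20000L) {
  stopifnot(nUpTruth >= 1L, nDownTruth >= 1L,
            detectProbNull >= 0, detectProbNull <= 1,
            detectProbFull >= 0, detectProbFull <= 1,
            length(backgroundFCRange) == 2L,
            backgroundFCRange[1L] >= 1, diff(backgroundFCRange) > 0,
            noiseSd >= 0, uploadFilter >= 1,
            universeN >= nUpTruth + nDownTruth)
  structure(list(nUpTruth = as.integer(nUpTruth),
                 nDownTruth = as.integer(nDownTruth),
                 signatureFCMeanlog = signatureFCMeanlog,
                 signatureFCSdlog = signatureFCSdlog,
                 signatureFCFloor = signatureFCFloor,
                 nBackgroundGenes = as.integer(nBackgroundGenes),
                 backgroundFCRange = backgroundFCRange,
                 detectProbNull = detectProbNull,
                 detectProbFull = detectProbFull,
                 noiseSd = noiseSd, uploadFilter = uploadFilter,
                 universeN = as.integer(universeN)),
            class = "GeneratorConfig")
}

#' Signature-gene detection probability as a function of effect strength
#'
#' Logistic interpolation between the null inclusion rate and the
#' full-effect inclusion rate of the configuration.
#'
#' @param effectAbs Absolute effect strength in \[0, 1\].
#' @param config A [generatorConfig()].
#' @return Inclusion probability vector.
#' @export
detectProb <- function(effectAbs, config = generatorConfig()) {
  stopifnot(all(effectAbs >= 0 & effectAbs <= 1))
  a <- stats::qlogis(config$detectProbNull)
  b <- stats::qlogis(config$detectProbFull) - a
  stats::plogis(a + b * effectAbs)
}

.syntheticUniverse <- function(config) {
  sprintf("G%05d", seq_len(config$universeN))
}

.drawBackgroundFC <- function(n, config) {
  r <- config$backgroundFCRange
  mag <- exp(stats::runif(n, log(r[1L]), log(r[2L])))
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Generate the planted "true" biomarker and its gene universe
#'
#' Draws the planted dimorphic signature: \code{nUpTruth} up- and
#' \code{nDownTruth} down-regulated genes placed in a synthetic universe of
#' \code{universeN} gene identifiers, with signed |fold-change| from the
#' configured log-normal law floored at the biomarker magnitude rule. Fully
#' deterministic under \code{seed}.
#'
#' @param config A [generatorConfig()].
#' @param seed Integer seed; \code{NULL} continues the current RNG stream.
#' @return List with elements \code{biomarker} (a
#'   [BiomarkerGeneSet-class]) and \code{universe} (character vector).
#' @export
makeTrueBiomarker <- function(config = generatorConfig(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nSig <- config$nUpTruth + config$nDownTruth
  if (nSig > config$universeN)
    stop("planted signature exceeds the universe size")
  universe <- .syntheticUniverse(config)
  genes <- sample(universe, nSig)
  mag <- pmax(config$signatureFCFloor,
              stats::rlnorm(nSig, config$signatureFCMeanlog,
                            config$signatureFCSdlog))
  fc <- mag * rep(c(1, -1), c(config$nUpTruth, config$nDownTruth))
  list(biomarker = BiomarkerGeneSet(genes, fc), universe = universe)
}

.truthLabel <- function(effect) {
  if (effect > 0) "activated" else if (effect < 0) "suppressed"
  else "unchanged"
}

#' Simulate one treatment bioset with known effect on the signature
#'
#' Each signature gene enters the bioset with probability
#' \code{detectProb(|effect|)}. For a nonzero effect its sign is the
#' biomarker sign times the effect sign (concordant for masculinizing,
#' flipped for feminizing) and its magnitude is the biomarker magnitude
#' jittered on the log scale; at zero effect the few signature genes that
#' appear behave as ordinary background (random sign, background
#' magnitude). Background noise genes with random signs and log-uniform
#' magnitudes are added, and the compendium upload filter
#' (|fold-change| >= 1.2) is applied last.
#'
#' @param truthBiomarker List from [makeTrueBiomarker()] (or a
#'   [BiomarkerGeneSet-class] plus \code{universe}).
#' @param effect Real in \[-1, 1\]: + masculinizing, - feminizing, 0 null.
#' @param config A [generatorConfig()].
#' @param seed Integer seed; \code{NULL} continues the current RNG stream.
#' @param id Bioset identifier.
#' @param annotation Optional [BiosetAnnotation-class].
#' @param universe Universe gene ids when \code{truthBiomarker} is a bare
#'   [BiomarkerGeneSet-class].
#' @return List with elements \code{bioset} ([Bioset-class]) and
#'   \code{truth} (one-row \code{data.frame}: bioset_id, effect,
#'   true_label).
#' @export
simulateBioset <- function(truthBiomarker, effect,
                           config = generatorConfig(), seed = NULL,
                           id = "synthetic", annotation = NULL,
                           universe = NULL) {
  if (is.list(truthBiomarker) && !is.null(truthBiomarker$biomarker)) {
    universe <- truthBiomarker$universe
    truthBiomarker <- truthBiomarker$biomarker
  }
  stopifnot(is(truthBiomarker, "BiomarkerGeneSet"), !is.null(universe),
            abs(effect) <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(annotation)) annotation <- BiosetAnnotation()

  bmGenes <- truthBiomarker@gene
  bmFC <- truthBiomarker@foldChange
  incl <- stats::runif(length(bmGenes)) < detectProb(abs(effect), config)
  sigGenes <- bmGenes[incl]
  if (effect != 0) {
    mag <- exp(log(abs(bmFC[incl])) +
               stats::rnorm(sum(incl), 0, config$noiseSd))
    sigFC <- mag * sign(bmFC[incl]) * sign(effect)
  } else {
    sigFC <- .drawBackgroundFC(sum(incl), config)
  }
  pool <- setdiff(universe, bmGenes)
  bgGenes <- sample(pool, min(config$nBackgroundGenes, length(pool)))
  bgFC <- .drawBackgroundFC(length(bgGenes), config)

  gene <- c(sigGenes, bgGenes)
  fc <- c(sigFC, bgFC)
  keep <- abs(fc) >= config$uploadFilter
  bioset <- Bioset(id, gene[keep], fc[keep], annotation)
  truth <- data.frame(bioset_id = id, effect = effect,
                      true_label = .truthLabel(effect),
                      stringsAsFactors = FALSE)
  list(bioset = bioset, truth = truth)
}

#' Simulate a labeled synthetic compendium
#'
#' Generates a planted biomarker plus \code{nActivated} concordant
#' (masculinizing), \code{nSuppressed} anti-concordant (feminizing) and
#' \code{nNull} null biosets with populated annotations (alternating sex,
#' synthetic factor names and accessions), so compendium screening,
#' grouping and validation are exercisable end to end. Byte-identical
#' output under the same seed.
#'
#' @param nActivated,nSuppressed,nNull Bioset counts per class.
#' @param effectMagnitude |effect| of the non-null biosets (default 0.9);
#'   recycled over biosets.
#' @param config A [generatorConfig()].
#' @param seed Integer seed fixing the whole stream (default 1).
#' @return List with \code{biomarker}, \code{universe}, \code{biosets}
#'   (list of [Bioset-class]) and \code{truth} (\code{data.frame}).
#' @export
simulateLabeledCompendium <- function(nActivated, nSuppressed, nNull,
                                      effectMagnitude = 0.9,
                                      config = generatorConfig(),
                                      seed = 1L) {
  stopifnot(nActivated >= 0L, nSuppressed >= 0L, nNull >= 0L)
  set.seed(seed)
  tb <- makeTrueBiomarker(config)
  effects <- c(rep(1, nActivated), rep(-1, nSuppressed), rep(0, nNull)) *
    rep_len(abs(effectMagnitude), nActivated + nSuppressed + nNull)
  n <- length(effects)
  biosets <- vector("list", n)
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    ann <- BiosetAnnotation(
      species = "mouse", tissueSystem = "liver",
      sex = if (i %% 2L == 1L) "male" else "female",
      factorCategory = "chemical",
      factorName = sprintf("compound_%03d", i),
      accession = sprintf("SYN%04d", i), inVivo = TRUE)
    sim <- simulateBioset(tb, effects[i], config,
                          id = sprintf("bs_%03d", i), annotation = ann)
    biosets[[i]] <- sim$bioset
    truths[[i]] <- sim$truth
  }
  list(biomarker = tb$biomarker, universe = tb$universe, biosets = biosets,
       truth = do.call(rbind, truths))
}

#' Simulate a male-vs-female comparison panel with knockout controls
#'
#' Emulates the input of biomarker construction: \code{nComparisons}
#' male-vs-female biosets in which every planted dependent gene (the
#' signature) appears in 4 to \code{nComparisons} comparisons with a
#' consistent sign and per-observation |fold-change| jittered then floored
#' at the biomarker magnitude rule (1.5) — so the selection rule holds by
#' construction — plus \code{nIndependentDimorphic} dimorphic genes that do
#' NOT depend on the knocked-out factor, and background noise. The knockout
#' comparisons omit the dependent genes entirely while the independent
#' dimorphic genes persist, so the dependence filter removes exactly the
#' independent set.
#'
#' @param config A [generatorConfig()].
#' @param nComparisons Number of male-vs-female comparisons (default 6).
#' @param nIndependentDimorphic Planted factor-independent dimorphic genes
#'   (default 20).
#' @param seed Integer seed (default 1).
#' @param minSupport Minimum per-gene support planted (default 4).
#' @param nKnockout Number of knockout comparisons (default 2).
#' @param backgroundPoolSize,nBackgroundPerComparison Size of the noise
#'   gene pool and noise genes drawn per comparison (defaults 8000, 100).
#' @return List with \code{panel} (a [ComparisonPanel-class]),
#'   \code{biomarker} (the planted dependent signature), \code{universe},
#'   \code{dependentGenes} and \code{independentGenes}.
#' @export
simulateMFPanel <- function(config = generatorConfig(), nComparisons = 6L,
                            nIndependentDimorphic = 20L, seed = 1L,
                            minSupport = 4L, nKnockout = 2L,
                            backgroundPoolSize = 8000L,
                            nBackgroundPerComparison = 100L) {
  set.seed(seed)
  tb <- makeTrueBiomarker(config)
  bm <- tb$biomarker
  floorFC <- config$signatureFCFloor

  # factor-independent dimorphic genes: same selection profile, but they
  # keep their dimorphism in the knockout
  pool0 <- setdiff(tb$universe, bm@gene)
  indGenes <- sample(pool0, nIndependentDimorphic)
  indFC <- pmax(floorFC,
                stats::rlnorm(nIndependentDimorphic,
                              config$signatureFCMeanlog,
                              config$signatureFCSdlog)) *
    sample(c(-1, 1), nIndependentDimorphic, replace = TRUE)

  dimGenes <- c(bm@gene, indGenes)
  dimFC <- c(bm@foldChange, indFC)
  nDim <- length(dimGenes)
  support <- sample(seq.int(minSupport, nComparisons), nDim, replace = TRUE)
  membership <- matrix(FALSE, nDim, nComparisons)
  for (i in seq_len(nDim))
    membership[i, sample.int(nComparisons, support[i])] <- TRUE

  bgPool <- sample(setdiff(pool0, indGenes), backgroundPoolSize)
  jitterFloor <- function(fc, n) {
    mag <- pmax(floorFC, exp(log(abs(fc)) + stats::rnorm(n, 0, config$noiseSd)))
    mag * sign(fc)
  }
  mkComparison <- function(idx, id, present) {
    g <- dimGenes[present]
    f <- jitterFloor(dimFC[present], sum(present))
    bg <- sample(bgPool, nBackgroundPerComparison)
    bgFC <- .drawBackgroundFC(nBackgroundPerComparison, config)
    ann <- BiosetAnnotation(sex = "unspecified",
                            factorCategory = "genetic",
                            factorName = "male vs female liver",
                            accession = sprintf("SYNMF%02d", idx))
    Bioset(id, c(g, bg), c(f, bgFC), ann)
  }
  comps <- lapply(seq_len(nComparisons), function(j)
    mkComparison(j, sprintf("mf_%02d", j), membership[, j]))
  isInd <- c(rep(FALSE, length(bm@gene)), rep(TRUE, nIndependentDimorphic))
  koComps <- lapply(seq_len(nKnockout), function(j)
    mkComparison(nComparisons + j, sprintf("ko_mf_%02d", j), isInd))
  list(panel = ComparisonPanel(comps, koComps), biomarker = bm,
       universe = tb$universe, dependentGenes = bm@gene,
       independentGenes = normalizeGene(indGenes))
}
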
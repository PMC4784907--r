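test_that("makeTrueBiomarker plants the configured signature deterministically", {
  tb <- makeTrueBiomarker(seed = 501)
  expect_equal(length(tb$biomarker), 144L)
  expect_equal(nUp(tb$biomarker), 74L)
  expect_equal(nDown(tb$biomarker), 70L)
  expect_true(all(abs(foldChanges(tb$biomarker)) >= 1.5))
  expect_length(tb$universe, 20000L)
  expect_true(all(geneIds(tb$biomarker) %in% tb$universe))
  # same seed -> identical output
  tb2 <- makeTrueBiomarker(seed = 501)
  expect_identical(foldChanges(tb$biomarker), foldChanges(tb2$biomarker))
  # planted sizes cannot exceed the universe
  expect_error(makeTrueBiomarker(generatorConfig(universeN = 100L)))
})

test_that("detectProb interpolates logistically between the configured rates", {
  cfg <- generatorConfig()
  expect_equal(detectProb(0, cfg), 0.05)
  expect_equal(detectProb(1, cfg), 0.95)
  e <- seq(0, 1, 0.1)
  expect_true(all(diff(detectProb(e, cfg)) > 0))
})

test_that("simulateBioset reaches its degenerate limits", {
  cfg <- generatorConfig(detectProbNull = 1e-9, detectProbFull = 1 - 1e-9,
                         noiseSd = 0)
  tb <- makeTrueBiomarker(cfg, seed = 502)
  # full effect, no noise, detection ~ 1: signature equals the biomarker
  sim <- simulateBioset(tb, effect = 1, config = cfg, seed = 503, id = "full")
  fc <- foldChanges(sim$bioset)
  bmFC <- foldChanges(tb$biomarker)
  expect_true(all(names(bmFC) %in% names(fc)))
  expect_equal(fc[names(bmFC)], bmFC)
  expect_equal(sim$truth$true_label, "activated")

  # full anti-concordant effect: every included signature gene flips sign
  simNeg <- simulateBioset(tb, effect = -1, config = cfg, seed = 504,
                           id = "neg")
  fcn <- foldChanges(simNeg$bioset)
  expect_equal(fcn[names(bmFC)], -bmFC)
  expect_equal(simNeg$truth$true_label, "suppressed")

  # null effect: signature genes appear only at the background rate
  simNull <- simulateBioset(tb, effect = 0, config = cfg, seed = 505,
                            id = "null")
  expect_length(intersect(geneIds(simNull$bioset), names(bmFC)), 0L)
  expect_equal(simNull$truth$true_label, "unchanged")
})

test_that("generated biosets always satisfy the invariants and upload filter", {
  cfg <- generatorConfig()
  tb <- makeTrueBiomarker(cfg, seed = 506)
  set.seed(507)
  for (eff in c(-1, -0.5, 0, 0.5, 1)) {
    sim <- simulateBioset(tb, eff, cfg, id = paste0("e", eff))
    expect_true(validObject(sim$bioset))
    expect_true(all(abs(foldChanges(sim$bioset)) >= cfg$uploadFilter))
  }
})

test_that("null signature inclusion matches the configured background rate", {
  cfg <- generatorConfig()
  tb <- makeTrueBiomarker(cfg, seed = 508)
  set.seed(509)
  nRep <- 1000L
  nSig <- length(tb$biomarker)
  hits <- 0L
  for (i in seq_len(nRep)) {
    sim <- simulateBioset(tb, 0, cfg, id = "n")
    hits <- hits + length(intersect(geneIds(sim$bioset),
                                    geneIds(tb$biomarker)))
  }
  rate <- hits / (nRep * nSig)
  se <- sqrt(cfg$detectProbNull * (1 - cfg$detectProbNull) / (nRep * nSig))
  expect_lt(abs(rate - cfg$detectProbNull), 3 * se)
})

test_that("simulateLabeledCompendium labels, annotates and reproduces", {
  sim <- simulateLabeledCompendium(0, 0, 10, seed = 510)
  expect_length(sim$biosets, 10L)
  expect_true(all(sim$truth$true_label == "unchanged"))
  expect_true(all(vapply(sim$biosets,
                         function(b) annotation(b)@species, "") == "mouse"))
  expect_setequal(vapply(sim$biosets, function(b) annotation(b)@sex, ""),
                  c("male", "female"))

  # same seed -> byte-identical bioset files
  sim2 <- simulateLabeledCompendium(0, 0, 10, seed = 510)
  f1 <- tempfile(); f2 <- tempfile()
  writeBioset(sim$biosets[[3]], f1)
  writeBioset(sim2$biosets[[3]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("strong planted effects are recovered end to end", {
  sim <- simulateLabeledCompendium(5, 5, 0, 0.9, seed = 511)
  calls <- vapply(sim$biosets, function(b)
    as.character(classifyStatus(directionalSimilarity(sim$biomarker, b))),
    character(1))
  expect_gte(sum(calls == sim$truth$true_label), 9L)
})

test_that("simulateMFPanel plants support and dependence by construction", {
  sim <- simulateMFPanel(seed = 512)
  expect_s4_class(sim$panel, "ComparisonPanel")
  expect_length(comparisons(sim$panel), 6L)
  expect_length(dependenceComparisons(sim$panel), 2L)
  # every planted dimorphic gene appears in at least 4 comparisons
  allGenes <- c(sim$dependentGenes, sim$independentGenes)
  support <- rowSums(vapply(comparisons(sim$panel),
                            function(b) allGenes %in% geneIds(b),
                            logical(length(allGenes))))
  expect_true(all(support >= 4))
  # dependent genes are absent from the knockout comparisons
  for (ko in dependenceComparisons(sim$panel))
    expect_length(intersect(geneIds(ko), sim$dependentGenes), 0L)
  # independent dimorphic genes persist there
  expect_true(all(sim$independentGenes %in%
                    geneIds(dependenceComparisons(sim$panel)[[1]])))

  # with no independent genes the dependence filter removes nothing
  sim0 <- simulateMFPanel(nIndependentDimorphic = 0L, seed = 513)
  cand <- selectConsistentGenes(sim0$panel)
  bm <- applyDependenceFilter(cand, dependenceComparisons(sim0$panel))
  expect_equal(sort(geneIds(bm)), sort(cand$gene))
})
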
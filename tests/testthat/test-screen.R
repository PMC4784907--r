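# A small labeled synthetic compendium shared by the screening tests.
screenFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateLabeledCompendium(3, 3, 4, 0.9, seed = 301)
      master <- buildMasterTable(sim$biomarker, sim$biosets)
      cache <<- list(sim = sim, master = master)
    }
    cache
  }
})

test_that("buildMasterTable yields one annotated row per bioset in fixed order", {
  fx <- screenFixture()
  master <- fx$master
  expect_equal(nrow(master), 10L)
  expect_equal(names(master),
               c("bioset_id", "species", "tissue", "sex", "factor_category",
                 "factor_name", "accession", "p_value", "direction",
                 "signed_score", "stat5b_call", "ahr_call", "car_call",
                 "pparalpha_call"))
  expect_true(all(master$ahr_call == "unknown"))
  # signed score consistent with p and direction
  expect_equal(master$signed_score,
               master$direction * -log10(pmax(master$p_value,
                                              .Machine$double.xmin)),
               tolerance = 1e-6)
  # strong planted effects are called correctly
  truth <- fx$sim$truth
  expect_equal(master$stat5b_call[match(truth$bioset_id, master$bioset_id)],
               truth$true_label)
})

test_that("the species/tissue filter drops non-mouse-liver biosets", {
  fx <- screenFixture()
  rat <- Bioset("rat1", c("A1", "A2"), c(2, -2),
                BiosetAnnotation(species = "rat"))
  other <- Bioset("oth1", c("A1", "A2"), c(2, -2),
                  BiosetAnnotation(tissueSystem = "other"))
  biosets <- c(fx$sim$biosets, list(rat, other))
  m <- buildMasterTable(fx$sim$biomarker, biosets,
                        restrictMouseLiver = TRUE)
  expect_false(any(c("rat1", "oth1") %in% m$bioset_id))
  expect_equal(nrow(m), 10L)
})

test_that("receptor predictions merge by id and unknown ids warn", {
  fx <- screenFixture()
  rp <- data.frame(bioset_id = c("bs_001", "no_such"),
                   ahr_call = c("activated", "activated"),
                   car_call = c("unchanged", "unknown"),
                   pparalpha_call = c("suppressed", "unknown"))
  expect_warning(
    m <- buildMasterTable(fx$sim$biomarker, fx$sim$biosets,
                          receptorPredictions = rp),
    "no_such")
  row <- m[m$bioset_id == "bs_001", ]
  expect_equal(row$ahr_call, "activated")
  expect_equal(row$pparalpha_call, "suppressed")
  expect_true(all(m$car_call[m$bioset_id != "bs_001"] == "unknown"))
})

test_that("summarizeFractions rounds percentages from the counts themselves", {
  # 45 feminized of 156 -> 29%
  master <- data.frame(
    sex = "male",
    stat5b_call = c(rep("suppressed", 45), rep("unchanged", 111)))
  s <- summarizeFractions(master, "sex")
  expect_equal(s$n_total, 156L)
  expect_equal(s$n_feminized, 45L)
  expect_equal(s$pct_feminized, 29)
  expect_equal(s$pct_masculinized, 0)

  # all unchanged -> 0% / 0%
  s0 <- summarizeFractions(data.frame(sex = "f", stat5b_call = "unchanged"),
                           "sex")
  expect_equal(s0$pct_feminized, 0)
  # empty master -> empty summary
  expect_equal(nrow(summarizeFractions(master[0, ], "sex")), 0L)
})

test_that("group counts are conserved across the summary", {
  fx <- screenFixture()
  s <- summarizeFractions(fx$master, c("sex", "factor_category"))
  expect_equal(sum(s$n_total), nrow(fx$master))
  expect_equal(s$pct_feminized, round(100 * s$n_feminized / s$n_total))
})

test_that("coModulationCrosstab reports co-activation and a disjoint Venn", {
  # 46 feminized rows: 43 with >= 1 receptor activated -> 93%
  ahr <- c(rep("activated", 10), rep("unchanged", 36))
  car <- c(rep("unchanged", 5), rep("activated", 25), rep("unchanged", 16))
  ppara <- c(rep("unchanged", 30), rep("activated", 13), rep("unchanged", 3))
  master <- data.frame(stat5b_call = rep("suppressed", 46),
                       ahr_call = ahr, car_call = car,
                       pparalpha_call = ppara)
  cm <- coModulationCrosstab(master)
  expect_equal(cm$nFeminized, 46L)
  expect_equal(cm$nFeminizedWithActivation, 43L)
  expect_equal(cm$pctFeminizedWithActivation, 93)
  expect_equal(sum(cm$venn), 43L)
  # rows 6-10 activate AhR and CAR -> counted once, in the intersection
  expect_equal(unname(cm$venn["AhR&CAR"]), 5L)
  expect_equal(unname(cm$venn["AhR"]), 5L)

  # all receptor calls unknown is an instructive error
  bad <- data.frame(stat5b_call = "suppressed", ahr_call = "unknown",
                    car_call = "unknown", pparalpha_call = "unknown")
  expect_error(coModulationCrosstab(bad), "receptor")

  # no feminized rows -> empty partition
  none <- data.frame(stat5b_call = "activated", ahr_call = "activated",
                     car_call = "unknown", pparalpha_call = "unknown")
  cm0 <- coModulationCrosstab(none)
  expect_equal(sum(cm0$venn), 0L)
  expect_equal(cm0$nFeminized, 0L)
})

test_that("heatmapMatrix orders genes by biomarker fold-change with NA sentinels", {
  bm <- BiomarkerGeneSet(c("A", "B", "C", "D"), c(4, 2, -1.5, -3))
  b1 <- Bioset("b1", c("A", "C"), c(3.5, -1.6))
  b2 <- Bioset("b2", geneIds(bm), unname(foldChanges(bm)))
  m <- heatmapMatrix(bm, list(b1, b2))
  expect_equal(rownames(m), c("A", "B", "C", "D"))
  expect_equal(colnames(m), c("b1", "b2"))
  expect_equal(sum(is.na(m[, "b1"])), 2L)
  expect_equal(unname(m[, "b2"]), c(4, 2, -1.5, -3))
  # export writes empty cells, never 0, for missing values
  path <- tempfile(fileext = ".tsv")
  writeHeatmapMatrix(m, path)
  lines <- readLines(path)
  expect_equal(strsplit(lines[3], "\t")[[1]][2], "")
})
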
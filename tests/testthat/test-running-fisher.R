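test_that("fisherExactOneSided matches analytic and enumerated tail values", {
  # no overlap: P(X >= 0) = 1
  expect_equal(fisherExactOneSided(0, 5, 5, 10), 1)
  # two 5-gene sets fully overlapping in a 10-gene universe
  expect_equal(fisherExactOneSided(5, 0, 0, 5), 1 / choose(10, 5))
  # enumerated oracle value
  expect_equal(fisherExactOneSided(3, 2, 2, 13), oracleUpperTail(3, 2, 2, 13))
  expect_error(fisherExactOneSided(-1, 2, 2, 2), "non-negative")
  expect_error(fisherExactOneSided(0, 0, 0, 0), "at least one")
})

test_that("fisherExactOneSided agrees with enumeration on random tables", {
  set.seed(101)
  for (i in 1:50) {
    cells <- sample(0:15, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1
    expect_equal(fisherExactOneSided(cells[1], cells[2], cells[3], cells[4]),
                 oracleUpperTail(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
  }
})

test_that("runningScan handles degenerate and closed-form cases", {
  # disjoint query and target: every cut has overlap 0 -> best p = 1
  r <- runningScan(c("A", "B"), c("X", "Y", "Z"), 100)
  expect_equal(r@bestP, 1)
  # empty query / target
  expect_equal(runningScan(character(0), c("X"), 100)@bestP, 1)
  expect_equal(runningScan(c("A"), character(0), 100)@overlapAtBest, 0L)
  # single-gene query at rank 1, single-cut grid: p = 1/N before correction
  N <- 250
  r1 <- runningScan("A", c("A", "X", "Y"), N, cutGrid = 1L)
  expect_equal(r1@bestP, 1 / N)
  expect_equal(r1@overlapAtBest, 1L)
})

test_that("runningScan matches the naive all-cuts oracle", {
  set.seed(102)
  # perfect nesting: query = the whole target set
  tgt <- sprintf("T%02d", 1:12)
  ora <- oracleRunningScan(tgt, tgt, 1000)
  r <- runningScan(tgt, tgt, 1000)
  expect_equal(r@bestP, ora$bestP, tolerance = 1e-12)
  expect_equal(r@bestCutRank, ora$bestCutRank)

  # random instances with <= 20-gene halves
  pool <- sprintf("P%02d", 1:40)
  for (i in 1:50) {
    tgt <- sample(pool, sample(2:20, 1))
    qry <- sample(pool, sample(1:20, 1))
    uni <- sample(50:500, 1)
    ora <- oracleRunningScan(qry, tgt, uni)
    r <- runningScan(qry, tgt, uni)
    expect_equal(r@bestP, ora$bestP, tolerance = 1e-10)
  }
})

test_that("the cut grid is dense up to 500 targets and sparse beyond", {
  expect_equal(defaultCutGrid(300), 1:300)
  g <- defaultCutGrid(5000)
  expect_lte(length(g), 100L)
  expect_true(all(diff(g) > 0))
  expect_equal(g[length(g)], 5000L)
})

test_that("a self-comparison is strongly concordant and sign-flip antisymmetric", {
  bm <- makeToyBiomarker(10, 10)
  self <- Bioset("self", geneIds(bm), unname(foldChanges(bm)))
  r <- directionalSimilarity(bm, self, universeN = 20000)
  expect_equal(direction(r), 1L)
  expect_lt(pValue(r), 1e-10)
  expect_gt(signedLogP(r), 10)

  flipped <- Bioset("flip", geneIds(bm), -unname(foldChanges(bm)))
  rf <- directionalSimilarity(bm, flipped, universeN = 20000)
  expect_equal(direction(rf), -1L)
  expect_identical(logPValue(rf), logPValue(r))   # exact quadrant relabeling
  expect_identical(signedLogP(rf), -signedLogP(r))
})

test_that("flipping biomarker signs equals flipping bioset signs", {
  set.seed(103)
  bm <- makeToyBiomarker(6, 6)
  bmFlip <- BiomarkerGeneSet(geneIds(bm), -unname(foldChanges(bm)))
  for (i in 1:10) {
    bs <- randomBioset(paste0("b", i), sample(5:15, 1), sample(5:15, 1),
                       pool = c(geneIds(bm), sprintf("N%02d", 1:30)))
    r1 <- directionalSimilarity(bmFlip, bs, 1000)
    bsFlip <- Bioset("fl", geneIds(bs), -unname(foldChanges(bs)))
    r2 <- directionalSimilarity(bm, bsFlip, 1000)
    expect_identical(logPValue(r1), logPValue(r2))
    expect_identical(direction(r1), direction(r2))
  }
})

test_that("the statistic is rank-based: rescaling magnitudes changes nothing", {
  set.seed(104)
  bm <- makeToyBiomarker(8, 8)
  bs <- randomBioset("sc", 12, 12,
                     pool = c(geneIds(bm), sprintf("N%02d", 1:40)))
  r1 <- directionalSimilarity(bm, bs, 2000)
  scaled <- Bioset("sc2", geneIds(bs),
                   sign(unname(foldChanges(bs))) *
                     abs(unname(foldChanges(bs)))^1 * 2.5)
  r2 <- directionalSimilarity(bm, scaled, 2000)
  expect_identical(logPValue(r1), logPValue(r2))
  expect_identical(direction(r1), direction(r2))
})

test_that("an empty biomarker half degrades gracefully, not an error", {
  bmUpOnly <- BiomarkerGeneSet(sprintf("U%d", 1:6), seq(2, 4, length.out = 6))
  bs <- Bioset("b", c("U1", "U2", "X1", "X2"), c(2, 3, -2, -1.5))
  r <- directionalSimilarity(bmUpOnly, bs, 500)
  expect_equal(quadrants(r)$down_up@bestP, 1)
  expect_equal(quadrants(r)$down_down@bestP, 1)
  expect_equal(direction(r), 1L)
})

test_that("signedLogP converts p and direction to the master-table score", {
  mkRes <- function(p, dir) {
    quad <- lapply(c("up_up", "up_down", "down_up", "down_down"),
                   function(q) new("QuadrantResult", quadrant = q, bestP = 1,
                                   logBestP = 0, bestCutRank = 0L,
                                   overlapAtBest = 0L, nCutsEvaluated = 0L))
    names(quad) <- c("up_up", "up_down", "down_up", "down_down")
    new("SimilarityResult", pValue = p, logPValue = log(p),
        direction = dir,
        signedScore = if (dir == 0L || p == 1) 0 else dir * -log10(p),
        quadrants = quad, overlapGenes = character(0))
  }
  expect_equal(signedLogP(mkRes(1e-4, 1L)), 4)
  expect_equal(signedLogP(mkRes(1e-6, -1L)), -6)
  expect_equal(signedLogP(mkRes(1, 1L)), 0)
  expect_equal(signedLogP(mkRes(1, -1L)), 0)
})

test_that("adding a concordant overlapping gene cannot worsen the evidence beyond the multiplicity accounting", {
  set.seed(105)
  concordantLogP <- function(r) {
    q <- quadrants(r)
    stats::pchisq(-2 * (q$up_up@logBestP + q$down_down@logBestP), df = 4,
                  lower.tail = FALSE, log.p = TRUE)
  }
  for (i in 1:40) {
    bm <- makeToyBiomarker(sample(3:8, 1), sample(3:8, 1))
    nUp <- sample(4:10, 1); nDn <- sample(4:10, 1)
    gUp <- c(sample(upGenes(bm), 2), sprintf("XU%d", seq_len(nUp)))
    gDn <- c(sample(downGenes(bm), 2), sprintf("XD%d", seq_len(nDn)))
    fUp <- runif(length(gUp), 1.2, 6)
    fDn <- -runif(length(gDn), 1.2, 6)
    bs <- Bioset("a", c(gUp, gDn), c(fUp, fDn))
    extra <- setdiff(upGenes(bm), gUp)
    if (!length(extra)) next
    bs2 <- Bioset("b", c(gUp, extra[1], gDn), c(fUp, runif(1, 1.2, 6), fDn))
    r1 <- directionalSimilarity(bm, bs, 500)
    r2 <- directionalSimilarity(bm, bs2, 500)
    # the uncorrected quadrant minima are monotone; the Bonferroni factor
    # can add at most log(ncuts2/ncuts1) per quadrant
    q1 <- quadrants(r1); q2 <- quadrants(r2)
    slack <- log(q2$up_up@nCutsEvaluated / q1$up_up@nCutsEvaluated)
    expect_lte(concordantLogP(r2), concordantLogP(r1) + slack + 1e-9)
  }
})
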
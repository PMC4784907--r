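# Independent brute-force oracles used to verify the package's statistics.
# These deliberately avoid the code paths (and distribution functions) that
# the implementation itself uses.

# Upper-tail hypergeometric probability P(X >= a) for the table
# [[a, b], [c, d]], computed by direct binomial-coefficient enumeration.
oracleUpperTail <- function(a, b, c, d) {
  m <- a + b            # query genes
  K <- a + c            # drawn
  n <- a + b + c + d
  ks <- a:min(m, K)
  if (a > min(m, K)) return(0)
  sum(choose(m, ks) * choose(n - m, K - ks)) / choose(n, K)
}

# Two-sided Fisher exact p: sum of probabilities of all tables with the
# observed margins whose point probability does not exceed the observed
# one (with the customary relative tolerance for ties).
oracleTwoSided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; K <- a + c; n <- a + b + c + d
  ks <- max(0, K - (n - m)):min(m, K)
  probs <- choose(m, ks) * choose(n - m, K - ks) / choose(n, K)
  pObs <- probs[ks == a]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Naive all-cuts running Fisher scan: loops over every cut in the grid,
# builds the 2x2 table explicitly and applies the Bonferroni correction.
oracleRunningScan <- function(queryGenes, targetRanked, universeN,
                              cutGrid = seq_along(targetRanked)) {
  q <- length(queryGenes)
  ps <- vapply(cutGrid, function(k) {
    a <- length(intersect(queryGenes, targetRanked[seq_len(k)]))
    b <- q - a
    c <- k - a
    d <- universeN - a - b - c
    oracleUpperTail(a, b, c, d)
  }, numeric(1))
  best <- which.min(ps)
  list(bestP = min(1, ps[best] * length(cutGrid)),
       bestCutRank = cutGrid[best],
       minUncorrected = ps[best])
}

# Small deterministic fixtures -----------------------------------------

makeToyBiomarker <- function(nUp = 4, nDown = 4) {
  BiomarkerGeneSet(c(sprintf("UP%d", seq_len(nUp)),
                     sprintf("DN%d", seq_len(nDown))),
                   c(seq(2, 5, length.out = nUp),
                     -seq(2, 5, length.out = nDown)))
}

# A random bioset over a synthetic namespace, with reproducible content.
randomBioset <- function(id, nUp, nDown, pool = sprintf("R%03d", 1:200)) {
  g <- sample(pool, nUp + nDown)
  fc <- c(runif(nUp, 1.2, 6), -runif(nDown, 1.2, 6))
  Bioset(id, g, fc)
}

writeBiosetLines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
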
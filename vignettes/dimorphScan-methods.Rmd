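---
title: "Methods: directional signature screening with the running Fisher test"
author: "dimorphScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: directional signature screening with the running Fisher test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorphScan)
```

# The data model

The unit of analysis is the **bioset**: a statistically filtered list of
differentially expressed genes from one two-condition comparison, each gene
carrying a signed *linear* fold-change. The linear convention (−1.2 means a
20% decrease; magnitudes are never below 1 and 0 is impossible) is enforced
by the `Bioset` class validity; log-ratio inputs must be converted at the
boundary. Gene identity is symbol-based after case-folding — probe-to-gene
collapsing, normalization and the upstream significance filter are
deliberately out of scope, because the pipeline's real-world inputs are
already filtered gene lists. Genes measured by multiple probes are assumed
pre-collapsed upstream; the reader rejects duplicate symbols rather than
guessing a resolution.

A **biomarker gene set** is a directional signature: genes with signed
average fold-changes, all with magnitude ≥ 1.5, partitioned into up- and
down-regulated halves by sign.

# Biomarker construction

`selectConsistentGenes()` operationalizes "robust, consistent dimorphism"
as three rules over a panel of replicate male-vs-female comparisons:

1. presence (= upstream significance) in at least `minSupport` comparisons
   (default 4 of 6);
2. an identical fold-change sign in *every* comparison where the gene
   appears — we apply the direction rule to all appearances, not only to
   the first four, which is the stricter of the two possible readings;
3. mean fold-change magnitude ≥ `minAvgAbsFC` (default 1.5), averaging only
   over the comparisons where the gene is present (absence is not imputed
   as "no change", since a missing gene may simply be off-platform).

`applyDependenceFilter()` then keeps a candidate only when its dimorphism
disappears in knockout male-vs-female comparisons: the gene must be absent
there or show residual |fold-change| below 1.2, the same threshold as the
compendium upload filter. The knockout requirement is stated qualitatively
in the screening literature; anchoring the residual limit to the upload
filter makes "no longer differential" mean exactly "would not have entered
the compendium".

`residualIntersection()` reports the biomarker genes still dimorphic after
two different interventions, reading "one or both of A and B" as
(A1 ∪ A2) ∩ B and additionally requiring a globally consistent sign across
every bioset where the gene appears — including between the two A members,
the stricter reading of an ambiguous rule.

# The directional running Fisher statistic

Similarity between a biomarker and a bioset is assessed by sign quadrant.
Both lists are split into up and down halves; each bioset half is ranked by
descending |fold-change| (ties broken lexicographically by gene id so the
ranking is deterministic). For a query half of size $q$ scanned along a
ranked target of length $T$ in a platform universe of $n$ genes, each rank
cut $k$ of the cut grid forms the table $a = |Q \cap \text{top-}k|$,
$b = q - a$, $c = k - a$, $d = n - a - b - c$, scored with the one-sided
hypergeometric upper tail $P(X \ge a)$. The quadrant statistic is
$\min_k p_k \times |\text{grid}|$, capped at 1.

Design choices where the published description defers to an external
algorithm, all fixed here and overridable by arguments:

* **Cut grid** — every rank when the target half has ≤ 500 genes, else 100
  evenly spaced ranks. Typical filtered biosets have a few hundred genes
  per half, so the scan is usually exhaustive; the sparse grid bounds cost
  on outliers at negligible loss, since neighbouring cuts are highly
  correlated.
* **Multiplicity over cuts** — Bonferroni, because the cut p-values are
  positively dependent, making the correction conservative; an empirical
  correction would need a null model the data do not provide.
* **Quadrant combination** — Fisher's method ($-2\sum\ln p$, $\chi^2$ with
  4 df) over the two same-direction quadrants; concordant = up↑up↑ +
  down↓down↓, discordant = the two cross terms.
* **Direction** — the sign of whichever combined p is smaller; an exact tie
  yields direction 0 and a zero score. Ties occur in practice only for
  degenerate inputs (e.g. no overlap at all, both combined p = 1).
* **Degenerate halves** — an empty query or target half is not an error:
  its quadrant returns best p = 1 and contributes nothing, so single-sided
  biomarkers and all-up biosets remain usable.
* **Universe** — default $n = 20000$, typical full-genome mouse array
  coverage; per-bioset override reflects platform coverage. Biomarker genes
  absent from a bioset contribute only through the universe margin; nothing
  is imputed.

Two exact symmetries follow from the construction and are enforced by
tests: flipping every bioset sign swaps the quadrant roles, flipping the
direction while preserving the p-value bit-for-bit; flipping biomarker
signs is equivalent to flipping bioset signs. Because only ranks enter,
rescaling all bioset magnitudes by a common factor changes nothing.

## Numerical behaviour

All p-values travel as natural logarithms (`phyper(log.p = TRUE)`,
`pchisq(log.p = TRUE)`), so compendium-scale scores — published screens
report similarity p-values down to $10^{-27}$, and a self-comparison at
$n = 20000$ reaches $10^{-400}$ — never underflow. The linear `pValue`
slot is derived by exponentiation and may underflow to 0 for display; the
log slot is authoritative and `signedLogP()` is computed from it.

One caveat is documented rather than hidden: the Bonferroni factor grows
with the cut grid, so adding a concordant overlapping gene to a bioset —
which always improves the *uncorrected* minimum p — can raise the
*corrected* quadrant p by up to the multiplicity ratio
$(|\text{grid}|+1)/|\text{grid}|$. The property test bounds the combined
concordant p by exactly this accounting.

# Classification and validation

`classifyStatus()` calls a bioset activated/masculinized when
$p \le 10^{-4}$ with concordant direction, suppressed/feminized when
anticorrelated, otherwise unchanged. The fixed $10^{-4}$ default mirrors
screening practice, where a Benjamini–Hochberg step-up at $\alpha = 0.001$
on the validation set yields a data-derived cutoff (2e−4 in the original
validation) that is rounded down to $10^{-4}$ for consistency across
biomarkers; `bhCutoff()` re-derives the step-up threshold on any user
compendium. Validation uses one-vs-rest balanced accuracy per class,
activation and suppression evaluated separately.

# The synthetic generator

`generatorConfig()` fixes the study conditions the package is tested
under; the defaults are chosen once, on biological grounds:

| parameter | default | rationale |
|---|---|---|
| signature sizes | 74 up / 70 down | the canonical dimorphic liver signature layout |
| signature \|FC\| | log-normal, meanlog log 2.5, sdlog 0.6, floor 1.5 | dimorphic liver genes span ~1.5× to >20× (Mup/Cyp-family extremes); the floor is the biomarker magnitude rule |
| background genes | 400 per bioset | a few hundred significant genes is typical of filtered liver comparisons |
| background \|FC\| | log-uniform on [1.2, 3] | modest noise changes; the lower edge makes the 1.2 upload filter observable but not vacuous |
| detection | logistic, 0.05 at no effect to 0.95 at full effect | signature genes drop out of significance lists as effects weaken; 5% is the false-inclusion background rate |
| noise | sd 0.15 on log FC | multiplicative jitter of ~±35% (2 sd), typical across platforms |
| universe | 20000 | matches the screening default |

`simulateBioset()` plants the signature concordantly (masculinizing,
effect > 0), anti-concordantly (feminizing, effect < 0) or not at all
(null), and at null the rare included signature genes behave as ordinary
background (random sign and magnitude). `simulateMFPanel()` builds the
biomarker-construction input with per-gene support drawn from {4, 5, 6}
and per-observation magnitudes jittered then floored at 1.5 — the floor is
a deliberate generator design: planted genes are defined to satisfy the
magnitude rule, so recovery failures indicate defects in the builder, not
borderline draws. Knockout comparisons omit dependent genes entirely while
factor-independent dimorphic genes persist.

What the generator does *not* emulate: probe-level intensity noise,
correlated gene modules, platform-specific coverage maps, batch effects,
or realistic annotation errors. Passing tests therefore demonstrate the
statistical machinery under the stated generative model — planted signal
recovery, null calibration, classification accuracy — not performance on
any particular real compendium.

# Problem sizes and test design

The test suite validates the exact statistics by independent enumeration
(all 2×2 tables with margins ≤ 12, exhaustively; 200 random scan instances
with ≤ 20-gene halves against a naive all-cuts oracle), symmetries on 100
random biomarker/bioset pairs, null calibration on 1000 generated null
biosets (empirical $P(p \le 0.05)$ within $0.05 + 3\,\mathrm{SE}$ and a
one-sided Kolmogorov–Smirnov check that the p distribution is
conservative), exact signature recovery across 20 generator seeds, and
classifier balanced accuracy on 100-bioset labeled compendia — sizes at
which the full suite runs in well under a minute while keeping every
Monte-Carlo margin wide.

# Known limitations

* The running Fisher internals here are a documented reconstruction of a
  proprietary implementation's published behaviour (direction, calibration,
  rank-basedness), not a bit-for-bit replica; absolute p-values may differ
  from platform outputs even when directions and orderings agree.
* The null distribution is conservative by construction (Bonferroni over
  dependent cuts, then a minimum over two combined statistics without a
  further factor-2 correction — the former effect dominates empirically);
  p-values should be read as screening scores, not calibrated tail
  probabilities.
* Sign-conflicting multi-probe genes, cross-species orthology and
  annotation quality are all upstream concerns the package trusts its
  inputs on.
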
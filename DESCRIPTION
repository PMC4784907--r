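Package: dimorphScan
Title: Biomarker-Based Screening of Liver Transcriptome Biosets for
    Masculinization and Feminization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for screening compendia of differential-expression gene
    lists ("biosets") against a sexually dimorphic liver gene expression
    biomarker. Implements a directional, fold-change rank-based running
    Fisher similarity statistic with quadrant decomposition, cutoff-based
    classification of biosets as masculinized (STAT5b-activated), feminized
    (STAT5b-suppressed) or unchanged, balanced-accuracy validation,
    compendium-level summaries and receptor co-modulation cross-tabs,
    single-gene enrichment against classification status, biomarker
    construction from replicate male-versus-female comparisons with a
    knockout-dependence filter, and a synthetic bioset generator with
    ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
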
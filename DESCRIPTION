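Package: vaxendo
Title: Pre-Vaccination Blood Transcriptomic Endotypes and Antibody Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for multi-study systems-vaccinology analyses of
    blood transcriptomes collected before and after vaccination. Provides
    within-study quantile normalization and cross-study batch correction
    estimated on pre-vaccination samples, principal variance component analysis
    (PVCA) with participant-level bootstrap confidence intervals, sample-level
    enrichment analysis (SLEA) z-scores against random-gene-set nulls,
    discovery and inflammatory labeling of pre-vaccination endotypes by
    hierarchical clustering with Gap-statistic model selection, antibody
    maximum-fold-change (MFC) response metrics with per-study high/low
    responder calls, a cross-validated random-forest response classifier with
    signature scoring and permutation significance, a seven-gene
    bacterial/viral etiology metascore, and endotype-stratified
    post-vaccination kinetics. A synthetic multi-study compendium generator
    with planted endotype, batch and kinetic structure supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    limma,
    lme4,
    randomForest,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster
Config/testthat/edition: 3
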
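Package: catransient
Title: Quantification of Population Calcium Transients in Larval Neurons
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies population calcium-imaging recordings of Drosophila
    larval neurons under nutrient (amino-acid) withdrawal. Provides a
    SummarizedExperiment-derived container for ROI fluorescence time series,
    dF/F normalization against an early-frame baseline, threshold-based
    responder classification, percent-responder summaries and segmental
    (T3-A5 hemisegment) topography, phase-windowed area-under-curve response
    metrics, and peptide-release quantification from fluorescence loss.
    Includes the accompanying statistical layer (Student t tests, one-way
    ANOVA with Tukey multiple comparisons and compact letter display,
    pupariation batch summaries, preference index), expression-side
    computations (a three-method consensus differential-expression gate and
    2^-ddCt qPCR fold changes), and a seeded synthetic-data generator that
    emulates the statistical structure of the experiments for testing and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, tools, S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, TimeCourse, Preprocessing, StatisticalMethod
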
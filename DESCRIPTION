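Package: epiphys
Title: Patch-Clamp Feature Extraction and an Ion-Channel Expression Funnel for
    mTOR-Dependent Epileptogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of cellular epileptogenesis in an inducible
    Tsc1-knockout model. Provides simulators and analysis for current-clamp
    excitability (F-I curves, rheobase, action-potential waveform features with
    a dV/dt threshold rule, spike-frequency adaptation ratio), voltage-clamp
    synaptic measures (miniature PSC detection by scaled-template matching,
    per-cell kinetics with an event-count inclusion rule, E/I ratios, and
    NMDA/AMPA current isolation at paired holding potentials), the study's
    statistical comparisons (mixed-design repeated-measures ANOVA, one-way
    ANOVA with many-to-one post hoc tests, t tests), and a transcriptomic
    funnel downstream of a count matrix (median-of-ratios normalization,
    negative-binomial Wald differential expression, curated-gene filtering,
    rapamycin-rescue classification, z-score heatmap clustering and PCA).
    Every analysis stage is exercised against ground-truth synthetic data
    generators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    ape,
    mvtnorm,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
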
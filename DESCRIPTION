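Package: esmtx
Title: Exponential Scale Mixture Models for Metatranscriptomic Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential expression analysis for metatranscriptomic (MTX)
    gene-family abundance tables with metagenomic (MGX) adjustment. Implements
    a scale mixture of exponential distributions (equivalently, a Lomax
    regression model) with subject-level random effects, left-censored
    treatment of zero abundances, a two-component inverse-gamma mixture for
    extreme sparsity, and spike-and-slab testing of the group effect. Posterior
    inference uses a Gibbs sampler with slice-sampling data augmentation;
    genes are ranked by posterior inclusion probability and the discovery list
    is truncated to control the Bayesian false discovery rate. Includes a
    Gaussian mixed-model comparator with configurable pseudocounts, readers
    and writers for HUMAnN-style stratified abundance tables, and a synthetic
    data generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
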
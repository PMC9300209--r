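Package: bulkCq
Title: Population Allele Frequency from qPCR Delta-Delta-Cq Measures on Bulk Samples
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interval estimation of a population allele frequency from
    Delta-Delta-Cq type real-time PCR measurements on multiple bulk (pooled)
    DNA samples. Individual DNA yields are modelled with a gamma distribution,
    so the allele ratio within a pool of m carriers among n individuals follows
    a beta distribution; the marginal likelihood of the two Delta-Cq observables
    per pool is a binomial mixture over the latent carrier count. Provides
    simultaneous maximum-likelihood estimation of the frequency, the gamma
    shape, the target-to-reference content ratio and the Cq measurement error
    with Wald confidence intervals from the observed information, calibration
    of auxiliary assay parameters from samples with known allele-mixing ratios
    (including incomplete designs), linearity and homoscedasticity diagnostics,
    and a seeded simulator and grid harness for power and coverage studies.
License: GPL (>= 3)
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
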
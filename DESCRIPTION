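Package: crossurv
Title: Two-Sample Tests for Crossing Survival Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements the major families of two-sample tests for
    right-censored survival data, with emphasis on alternatives in which
    the survival curves cross: weighted log-rank tests (log-rank,
    Gehan-Wilcoxon, Tarone-Ware, Fleming-Harrington G^rho,gamma) and
    Lee's combined versatile tests; supremum and integral statistics on
    the cumulative-hazard scale (Renyi, modified Kolmogorov-Smirnov,
    censored Cramer-von Mises); Kaplan-Meier difference tests
    (Pepe-Fleming weighted Kaplan-Meier, Shen-Cai maximum weighted
    Kaplan-Meier, Lin-Xu area test, Lin-Wang squared observed-expected
    test); the Qiu-Sheng two-stage procedure; and Kraus's adaptive
    Neyman smooth tests with permutation calibration.  A simulation
    module generates crossing-curve benchmark scenarios with calibrated
    uniform censoring, and a Monte Carlo harness estimates size and
    power of any registered test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), survival, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
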
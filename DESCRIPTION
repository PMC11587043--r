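Package: critpow
Title: Critical Power and W' Estimation from All-Out and Constant-Power
    Cycling Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for estimating the two parameters of the critical power
    model -- critical power (CP, the asymptote of the power-duration
    relationship) and W' (the finite work capacity above CP) -- from cycle
    ergometer power-time traces.  Implements the traditional power-1/time
    regression, analysis of the 3-minute all-out test (end power and the
    power-time integral above it), and the constant-power plus all-out test
    protocol: failure-point and plateau segmentation of the trace and the
    partition of W' into constant-power and unaccounted components.  Includes
    a synthetic trace simulator with known ground truth for every stage,
    repeated-measures group comparisons under compound symmetry with
    Dunnett many-to-one and Bonferroni adjustment, and an end-to-end cohort
    pipeline producing summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    lme4,
    lmerTest,
    multcomp,
    mvtnorm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
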
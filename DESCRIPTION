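Package: l1census
Title: Intragenic and Intergenic Full-Length LINE-1 Census and Association Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing full-length LINE-1 (L1) retrotransposons located
    inside gene bodies (intragenic) with those outside (intergenic). Classifies
    elements against gene annotation, computes L1 densities per chromosome class
    in counts per megabase, screens L1 structural features for conservation
    differences using subfamily-stratified Mantel-Haenszel chi-square tests with
    Mantel-Haenszel odds ratios and Robins-Breslow-Greenland confidence
    intervals, compares quantitative features by Welch unequal-variance t-tests,
    and tests whether intragenic-L1 presence is associated with down-regulation
    of host genes across early embryonic stages via paired t-test differential
    expression and 2x2 chi-square association with Woolf confidence intervals.
    A synthetic-data generator emulates genome annotation, L1 feature tables and
    staged expression matrices with planted effects, supporting type-I
    calibration and parameter-recovery studies without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
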
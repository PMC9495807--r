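Package: copindval
Title: Indicator-Species and Water-Mass Analysis of Copepod Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delimiting coastal water masses from hydrographic
    measurements and identifying the zooplankton taxa that indicate them.
    Implements community dominance statistics (mean abundance, relative
    abundance, occurrence rate, order-level composition), Bray-Curtis
    environmental clustering with a similarity-profile permutation test,
    one-way ANOVA with Tukey HSD contrasts of station totals, the
    Dufrene-Legendre indicator value (IndVal = specificity x fidelity x 100)
    with permutation inference and a consistency solver for published IndVal
    tables, and a DCA-gated redundancy analysis of dominant taxa on
    temperature, salinity, dissolved oxygen and pH.  A synthetic community
    generator with planted indicator species provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
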
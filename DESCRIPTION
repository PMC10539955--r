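Package: gngmida
Title: Fractional Gluconeogenesis from Heavy-Water Labeling by Mass
    Isotopomer Distribution Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generative combinatorial model of deuterium mass-isotopomer
    labeling of the glucose methoxyamine-pentaacetate GC-MS fragment under
    mixtures of glucose-production pathways, and the inverse estimators built
    on it. Computes natural-abundance isotopologue baselines by convolution,
    excess mass-isotopomer enrichments (EM1, EM2) and their ratio R = EM2/EM1,
    generates EM2/EM1 lookup tables over body-water enrichment and fractional
    gluconeogenesis, inverts measured ratios to f(GNG) and to subpathway
    contributions (PEPCK vs glycerol gluconeogenesis), estimates body-water
    enrichment from acetone standard curves, and reproduces the method's
    sensitivity analyses (glycerol-contribution variation, transaldolase and
    pentose-phosphate exchange, equivalent site-count mixing curves). Includes
    a forward simulator of noisy three-ion spectra so the estimators can be
    validated without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
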
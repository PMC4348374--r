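Package: t2dmarkov
Title: Multi-State Markov Projection of Type 2 Diabetes Prevalence
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Annual-cycle multi-state Markov cohort model projecting type 2
    diabetes (T2D) prevalence from demographic change plus obesity and smoking
    trends. Implements Barendregt-style partition of all-cause mortality by
    disease status, DisMod-style back-calculation of T2D incidence from
    prevalence, mortality and relative mortality, geometric risk-factor trend
    extrapolation with capping, phased policy-scenario overlays, and
    analysis-of-extremes sensitivity. Ships the Tunisian 1997/2005 survey
    anchors as a packaged fixture together with a synthetic-data generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
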
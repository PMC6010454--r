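Package: bcifes
Title: Closed-Loop Brain-Computer Interface with Functional Electrical
    Stimulation: Decoding, Connectivity and Clinical Outcome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sham-controlled brain-computer interface
    (BCI) therapies that couple sensorimotor-rhythm decoding to functional
    electrical stimulation (FES) in stroke rehabilitation. Implements the
    online decoding chain (surface Laplacian, Welch power-spectral-density
    features, discriminant-power feature ranking, a two-class Gaussian
    classifier with leaky evidence accumulation and a confidence
    threshold), short-time direct directed transfer function (SdDTF)
    effective connectivity from multi-trial multivariate autoregressive
    fits, decoder-FES contingency tables with leave-one-out regression on
    recovery, and the clinical statistical battery (mixed-design ANOVA,
    Wilcoxon tests, odds ratios with Woolf intervals, Pearson
    correlations, Lilliefors normality checks). A synthetic-data module
    generates event-related-desynchronisation EEG with known ground
    truth, closed-loop and sham therapy sessions, and clinical cohorts;
    per-patient clinical score tables are packaged as plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    nortest
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
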
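Package: ucbridge
Title: Usefulness-Criterion Prediction and Donor Selection in Maize Bridging Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for genomic prediction in multiparental BC1S2 bridging
    designs that introduce genetic-resource donors into elite maize breeding
    material. Simulates genetic maps, inbred parents, BC1S2 families
    (Haldane meiosis, single-seed descent) and additive traits; estimates
    per-family means and additive variances by REML with NOIA marker-based
    kinship; predicts unobserved individuals by GBLUP under alternative
    training-set compositions; estimates marker effects by Bayesian ridge
    regression (Gibbs sampling); predicts the mean, progeny variance (VPM
    and PMV) and usefulness criterion of untested donor x recipient crosses
    from the parental linkage-disequilibrium and expected BC1S2
    recombination; and prioritizes new donors with a haplotype-window H
    criterion under forward selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
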
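Package: sliceMFA
Title: Steady-State 13C Metabolic Flux Analysis for Ex Vivo Tissue Cultures
Version: 0.1.0
Authors@R:
    person("Nilsson Lab", "Artifacts", email = "artifacts@example.org",
           role = c("aut", "cre"))
Description: A pipeline for quantifying metabolic fluxes in cultured tissue
    slices from 13C isotope tracing and medium exchange data. Reads
    atom-mapped metabolic network models in the OpenFLUX sheet dialect,
    simulates steady-state mass-isotopomer distributions via the elementary
    metabolite unit (EMU) framework with compartment and spent-medium
    mixtures, corrects measured mass-isotopomer distributions for natural
    13C abundance, quantifies metabolite uptake and release rates (including
    isotope-dilution quantification), fits network fluxes by weighted least
    squares with chi-square goodness-of-fit assessment, computes
    profile-likelihood confidence intervals and substrate-to-product carbon
    flows, and contrasts labeling-based estimates with label-free flux
    variability analysis. Includes a synthetic-data generator emulating
    deep-labeling tracer experiments on a liver-like toy network, and
    scoring of genome-scale model reactions from gene-level z-scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    boot,
    jsonlite,
    xml2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
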
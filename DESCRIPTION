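Package: targdecon
Title: Target Deconvolution and Time-Course iTRAQ Quantification for
    Chemical Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for peptide-drug proteomics built around
    the CIGB-552 antitumor peptide workflow: deconvolution of affinity
    purification (AP-MS) hit lists by subtraction of matrix binders and
    central-proteome proteins with CRAPome spectral-count annotation;
    emPAI abundance indices from in-silico tryptic digestion and
    emPAI-proportional drug-affinity scores; 4-plex iTRAQ reporter-ion
    ratio fitting by non-negative deconvolution of isotopic envelopes
    with a goodness-of-fit filter; median/SD differential-expression
    thresholds over a treatment time course with ON/OFF calls;
    hypergeometric functional enrichment with Benjamini-Hochberg FDR;
    and affinity-weighted perturbation scores for functional subnetworks
    of an interactome. A synthetic-data module generates every input
    with known ground truth so each stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
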
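Package: cspscreen
Title: Protein-Observed NMR Fragment Screening and Chemical Shift
    Perturbation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for protein-observed NMR fragment screens:
    reads assigned 2D (1H-15N HSQC) peak lists, computes weighted chemical
    shift perturbations (CSPs) against a reference state, triages fragment
    mixtures, calls deconvolution hits with a counted-resonance rule, fits
    titration CSPs to the ligand-depletion (quadratic) binding isotherm per
    residue and globally with a shared apparent Kd, classifies fragments as
    specific, weak, or nonspecific binders, compares conditions, and maps
    per-residue CSPs onto structure annotations and PDB B-factors. Includes
    a seeded synthetic-data generator that emulates fast-exchange two-state
    binding with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
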
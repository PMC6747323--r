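Package: pepscreen
Title: In Silico Proteolysis and Screening of ACE-Inhibitory Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates exhaustive enzymatic hydrolysis of proteins under
    declarative cleavage-specificity rules (subsite accept/block patterns,
    substrate-length constraints, sequential digestion), computes quantitative
    release statistics (degree of hydrolysis, release frequency A_E, relative
    release frequency W), annotates peptides with angiotensin-converting
    enzyme (ACE) inhibitory activity by reference lookup and pluggable
    predictors, and screens candidates through a multi-stage cascade:
    gastrointestinal stability with fragment re-entry, allergenicity and
    toxicity predicates, and rule-of-5 intestinal permeability from
    sequence-derived physicochemical properties. Also provides dose-response
    analysis for ACE inhibition assays (calibration curves, inhibition
    percentage, IC50 and pIC50 estimation) and conformational metrics on
    coordinate trajectories (RMSD with Kabsch superposition, per-residue RMSF,
    radius of gyration, Shrake-Rupley solvent-accessible surface area,
    geometric hydrogen-bond counting, metal-coordination distances, and an
    equilibration check), plus seeded synthetic-data generators so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    minpack.lm,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
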
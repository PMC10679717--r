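Package: ttmd
Title: Thermal Titration Molecular Dynamics Analysis for Nucleic
    Acid-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for ranking nucleic-acid-ligand binding poses by the
    persistence of native interactions across a temperature ramp (thermal
    titration molecular dynamics, TTMD). Detects residue-level
    receptor-ligand interactions (hydrogen bonds, pi stacking, ionic,
    hydrophobic, halogen and van der Waals contacts) with explicit
    pharmacophoric typing for RNA, encodes them as fixed-layout
    interaction fingerprints, scores every trajectory frame against a
    reference with the negated cosine similarity (IFP_CS), and summarises
    runs with the MS (titration-profile slope) and IFF (fingerprint
    fluctuation) stability coefficients. Includes trimmed replicate
    aggregation and pose ranking, RMSD titration timelines and profiles,
    a pluggable simulation-engine contract with a toy Langevin backend,
    declarative equilibration-stage configurations, a receptor-only dry
    run, and synthetic fingerprint/trajectory generators for desk-scale
    validation and parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
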
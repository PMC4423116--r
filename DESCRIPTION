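Package: ToxinScan
Title: Membrane Partitioning, Channel Occupancy and Interface Mapping for
    Cystine-Knot Toxins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of how inhibitor-cystine-knot (ICK)
    tarantula toxins engage lipid membranes and ion-channel binding surfaces.
    Fits mole-fraction membrane partition coefficients (K_x, K_dx) and
    Stern-Volmer quenching constants (K_sv) to tryptophan-fluorescence
    titrations; converts steady-state current inhibition at weak
    depolarizations into fraction unbound, apparent K_d under a
    four-independent-site occupancy model, and alanine-scan perturbation
    energies (DDG); and maps channel-binding surfaces geometrically via
    Kabsch superposition, Shrake-Rupley solvent-accessible surface area,
    per-residue interface burial (DSASA), hydrophobic patch clustering, and
    register-shifted grafting of a toxin onto a target helix with steric
    clash screening. A seeded synthetic-data module emulates the spectra,
    titrations, inhibition experiments and toy helix-toxin complexes the
    analyses assume, so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'occupancy.R'
    'spectro.R'
    'structmap.R'
    'synthdata.R'
    'utils.R'
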
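Package: mmpbsar
Title: Rescoring Toolkit for End-State MMPBSA Binding Free Energies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-scoring machinery for single-trajectory MMPBSA binding
    free energies. Provides Monte-Carlo probe estimators for accessible
    surface area and the probe-centered and probe-occupiable accessible
    volumes of molecular structures, a deterministic lattice oracle for
    validating them, the family of empirical binding-free-energy
    estimators built on decomposed end-state energy terms (one-term,
    two-term cavity-dispersion, scaled-particle-theory, PBSA_E and its
    extended form, and machine-learned single-point-energy variants),
    two-valued interior-dielectric rescaling, coefficient fitting against
    experimental affinities, and the ranking metrics used in virtual
    screening (predictive index, Pearson and Spearman correlation, and
    the mean-unsigned-error family).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
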
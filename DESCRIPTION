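Package: idpbind
Title: Coarse-Grained Simulation of Coupled Folding and Binding of
    Disordered Peptides with Screened Electrostatics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds flavored C-alpha structure-based (Go-like) models of a
    folded receptor bound to an intrinsically disordered peptide, adds
    Debye-Huckel screened electrostatics on charged residues, and propagates
    them with Langevin dynamics, optionally biased along a smooth
    fraction-of-native-contacts coordinate (umbrella sampling or
    well-tempered metadynamics).  Includes WHAM and metadynamics reweighting
    for free-energy surfaces and binding free energies, structural
    observables (native-contact fractions, radius of gyration, helix
    content, distance maps, charged-contact classification,
    encounter-complex detection), first-passage-time binding kinetics across
    ionic strengths, polyampholyte sequence-charge metrics, and a
    synthetic mini-complex generator so the whole pipeline runs without
    external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
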
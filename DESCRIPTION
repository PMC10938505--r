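Package: rnahcg
Title: Hierarchical Chain Growth of Single-Stranded RNA Ensembles
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds atomistic conformational ensembles of disordered
    single-stranded RNA by hierarchical chain growth (HCG) from tetramer
    fragment libraries, using weighted Kabsch superposition at fragment
    junctions and excluded-volume (steric clash) rejection. Includes a
    synthetic fragment-library generator based on idealized A-form
    internal coordinates, fluorophore (dye) mapping for FRET forward
    models, Debye-formula SAXS intensities with Guinier analysis,
    base-stacking quantification, and Bayesian/maximum-entropy ensemble
    reweighting (BioEn) against SAXS profiles and scalar FRET means.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
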
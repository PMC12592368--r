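Package: ionbindr
Title: Divalent Cation Binding Sites and Standard Binding Free Energies
    from Metadynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying divalent cation (Mg2+, Ca2+) binding to ion
    channels and model compounds. Scans protein structures for acidic-residue
    coordination sites using a Calpha-distance criterion, profiles pore radii,
    runs desk-scale well-tempered metadynamics on analytically tractable
    binding landscapes with multiple walkers and flat-bottom restraints,
    reweights biased samples to free-energy surfaces, extracts minimum
    free-energy paths by the zero-temperature string method, and assembles
    standard binding free energies from 1D potentials of mean force with
    restraint-volume and limiting Debye-Hueckel ionic-strength corrections
    and block-analysis errors. Reads and writes PLUMED-dialect COLVAR/HILLS
    files and PDB/mmCIF coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    digest,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
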
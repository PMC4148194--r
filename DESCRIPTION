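Package: epsolid
Title: Volumetric Comparison of Electrostatic Fields in Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns electrostatic potential fields and molecular geometry into
    boolean-composable volumetric solids. Isopotential surfaces are extracted
    from scalar fields on regular cubic lattices by marching cubes, closed into
    solids, and combined with cavity and interface geometry through
    constructive solid geometry (intersection, union, difference).  On top of
    this volume algebra the package compares binding-cavity electrostatics,
    measures electrostatic complementarity across protein-protein interfaces,
    scans residues by charge nullification to find electrostatically
    influential amino acids, and clusters binding cavities by Jaccard distance
    with UPGMA dendrograms.  Includes a screened-Coulomb and a finite-difference
    linearized Poisson-Boltzmann potential model, PQR/PDB readers, OpenDX grid
    import/export, and a deterministic synthetic-fixture generator with planted
    ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
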
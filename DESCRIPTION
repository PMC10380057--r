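Package: ctna
Title: Conformational Transition Networks and Solvation Analysis for
    Molecular Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds descriptor-based conformational transition networks from
    molecular dynamics trajectories of intrinsically disordered peptides:
    per-frame secondary-structure descriptors (helical and sheet residue
    counts, end-to-end distance), projection onto discrete states, directed
    transition-count matrices, modularity community detection, and export to
    graph formats readable by Gephi. Companion solvation analyses include
    oxygen-oxygen radial distribution functions, the translational and
    tetrahedral orientational water order parameters, hydrogen-bond lifetime
    autocorrelation with stretched-exponential fits and gamma-function mean
    lifetimes, residue contact-probability maps, ion radial distributions
    around charged groups, and formal net charges of peptides and
    glycosaminoglycan chains. A synthetic-data module generates
    Markov-switching peptide trajectories with geometry-backed secondary
    structure, water-oxygen configurations spanning ideal-gas to
    diamond-lattice order, renewal-process hydrogen-bond traces, and toy ion
    systems with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    igraph,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr,
    optparse
Config/testthat/edition: 3
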
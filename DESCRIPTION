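Package: nucleoslide
Title: Nucleosome Repositioning Analysis from Site-Specific Cleavage Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how local DNA perturbations steer nucleosome
    repositioning by the Chd1 chromatin remodeler. Builds perturbation
    libraries (poly(dA:dT) tracts, consecutive mismatches, single-nucleotide
    insertions) on a positioning sequence, simulates site-specific
    photo-cleavage sequencing reads with known ground truth, calls nucleosome
    dyad distributions from strand-specific cleavage profiles, decomposes
    positioning signals by nonnegative matrix factorization, clusters them by
    Jensen-Shannon similarity, maps Kullback-Leibler divergences onto
    perturbation coordinates, estimates twist-defect free-energy costs from
    defect-coordinate series, and solves a master-equation model of
    bidirectional remodeler-driven sliding with its effective free-energy
    landscape and remodeling-barrier metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    cluster,
    graphics,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
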
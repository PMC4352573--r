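Package: apfp3d
Title: Stereoselective 3D Atom-Pair Fingerprints for Ligand-Based Virtual
    Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes scalar atom-pair fingerprints of 3D molecular structures
    using gaussian distance sampling (3DAPfp, 3DXfp) or regular 0.5 Angstrom
    distance binning (R3DAPfp, R3DXfp), their topological 2D parents (APfp,
    Xfp), and the comparison shape descriptors USR, USRCAT and PMIfp.  Provides
    city-block-distance nearest-neighbour search over fingerprint databases
    using a bit-sum hash index, pharmacophore atom typing (hydrophobic,
    H-bond donor/acceptor, planar), evaluation metrics for virtual-screening
    benchmarks (ROC AUC, enrichment factors, shape-triangle occupancy,
    nearest-neighbour overlap of diastereomer searches), synthetic toy-molecule
    generators for exact testing, and an 'apfp3d' command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    methods,
    optparse,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
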
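Package: colmech
Title: Mechanical Stress and Redox Chemistry of Crosslinked Collagen Fibrils
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained modelling and analysis of mechanical stress
    concentration and redox chemistry in crosslinked collagen I fibrils.
    Builds D-periodic bead-per-residue fibril segments with
    hydroxylysino-keto-norleucine (HLKNL) crosslinks, runs overdamped
    Langevin constant-force pulling simulations, recomputes time-averaged
    pairwise bond forces and their residue-windowed profiles along
    crosslink-connected triple-helix pairs, maps multiple-sequence-alignment
    counts of redox-active residues (Tyr/Phe/Met) onto axial fibril slices,
    computes radial distribution functions of redox-active residues around
    crosslinks, simulates powder EPR spectra from g-tensors with extraction
    of effective g-factor, peak-to-peak linewidth, signal size and spin
    counts, and quantifies hydrogen peroxide differences from ferrous
    oxidation-xylenol orange (FOX) absorbance plates, including the tensile
    stress/force arithmetic. Synthetic-data generators for trajectories,
    alignments, EPR sweeps and absorbance plates make every analysis
    runnable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    Biostrings,
    bio3d,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: StructuralBioinformatics, Proteomics, Alignment, Software
RoxygenNote: 7.3.3
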
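Package: fibrilbreak
Title: Beta-Sheet Breaker Peptide Libraries and Amyloid Protofibril
    Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for designing hexapeptide beta-sheet breakers and for
    quantifying their destabilizing effect on U-shaped amyloid-beta
    protofibril models. Provides combinatorial peptide library generation,
    an idealized five-chain protofibril builder with a stochastic
    trajectory simulator, geometric detectors for hydrogen bonds, salt
    bridges and aromatic ring stacking with occupancy statistics,
    RMSD, radius-of-gyration and secondary-structure analyses,
    hierarchical average-linkage clustering with Davies-Bouldin, pseudo-F
    and explained-variance indices, and a single-trajectory MM-GBSA
    binding free energy decomposition with a self-contained generalized
    Born and LCPO surface-area backend.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
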
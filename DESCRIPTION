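Package: lipscan
Title: Detection of Light Interfaces of High Polarity (LIPs) in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sliding-window analysis of monomeric protein 3D structures to locate
    buried interfaces of high polarity and low packing density (LIPs), the loci of
    local unfolding and late folding events. For every 8-residue probe fragment the
    package computes the polar/apolar buried surface area ratio at the
    fragment-versus-remainder interface (deterministic accessible-surface engine,
    1.4 Angstrom probe) and the interface packing density (standard over actual
    radical-plane Voronoi atomic volumes with solvent capping), assembles
    per-residue profiles, calls LIP intervals with the 0.8 peak / 0.5 baseline /
    mean-minus-2SD packing rule, and provides the associated rank-sum statistics,
    reference core/surface polarity baselines, profile projection onto multiple
    alignments, synthetic-structure fixtures and validation oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
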
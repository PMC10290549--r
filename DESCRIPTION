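Package: nfcluster
Title: Network-Free Stochastic Simulation and Statistics of Multivalent
    Molecular Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates supply-limited clustering of multivalent biomolecules
    by exact network-free stochastic simulation (Gillespie direct method) of
    reversible site-site binding rules written in a restricted BioNetGen
    (BNGL) dialect, and statistically characterizes the resulting molecular
    clusters across many stochastic trials: molecule-weighted cluster-size
    (occupancy) distributions and average cluster occupancy, binned size
    histograms, bonds-per-molecule distributions overall and per molecule
    type, bound-fraction-by-size frequency matrices, per-size cluster
    composition, and mean/standard-deviation envelopes of observable time
    courses. Reads and writes NFsim-style output files (observable time
    courses and final-species lists) so externally produced runs can be
    analyzed with the same tools.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
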
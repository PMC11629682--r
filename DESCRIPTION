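Package: mecphage
Title: Phage-Host Association Analysis for Microbial Electrolysis Cell Metagenomes
Version: 0.1.0
Authors@R:
    person("MEC", "Virome Project", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale reimplementation of a metagenomic phage-host
    association workflow for microbial electrolysis cells (MECs): ANI-based
    dereplication of genome bins and phage contigs into species clusters,
    CRT-style CRISPR array detection and spacer-protospacer matching,
    homology-based prophage calling and induction detection against a
    virus-like-particle (VLP) dataset, electrode-affiliation classification
    from relative abundance profiles, host-phage association networks, and
    Hill-number beta-diversity statistics with PCoA and Mantel tests. A
    ground-truthed synthetic community generator drives end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
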
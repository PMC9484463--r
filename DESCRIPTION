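Package: mircrosstalk
Title: miRNA-miRNA Crosstalk Networks from Population Variant Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers cooperative miRNA-miRNA interactions in natural plant
    populations from genome-wide sequence variants. Variants within mature
    miRNAs and their target binding sites are applied to per-ecotype
    pseudo-sequences, target sites are re-predicted with two independent
    complementarity scorers, and every miRNA-target regulation receives a
    per-ecotype regulation fate profile (kept, lost, gained). Pairs of miRNAs
    whose regulations toward a common target co-occur across ecotypes are
    scored with a co-regulation (coreg) score and assembled into a crosstalk
    network with static/dynamic crosstalk typing. Includes randomization
    Z-score enrichment tests, network topology (hubs, bottlenecks, bridges),
    expression-based threshold sweeps, stress-sharing and climatic
    permutation tests, and a fully synthetic panel generator with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
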
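Package: ldassoc
Title: Integrated Regional Association Plots with Gene Structure and
    Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combines a regional (or single-gene) marker-trait association
    scatter, a gene-structure track, and a Haploview-style triangle linkage
    disequilibrium (LD) heatmap into one aligned figure with linking lines.
    Reads genotypes in HapMap text format, gene models from GTF, and
    association results from delimited tables; estimates pairwise LD (D,
    |D'|, r-squared) from unphased diploid genotypes by EM haplotype-
    frequency estimation, optionally from a genotype panel different from
    the association panel; includes a seeded haplotype-block simulator so
    every component is testable without external data, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    graphics,
    stats,
    utils,
    tools,
    yaml,
    optparse,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
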
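Package: dagpeaks
Title: ChIP-Seq Peak Calling on Directed Acyclic Variation Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls ChIP-seq peaks on reads aligned to a directed acyclic
    variation graph (a pangenome reference), generalizing the MACS2
    linear pipeline: strand cross-correlation fragment-length estimation
    on the busiest linear path, breadth-first fragment extension along
    all graph paths, a projected local-lambda Poisson background track,
    per-base p/q scoring with Benjamini-Hochberg FDR control, gap
    filling, connected peak-subgraph extraction and maximum-read-support
    path reporting with summits.  Includes readers and writers for
    vg-style JSON graphs, GFA1 and GAM JSON-lines alignments,
    graph-to-linear coordinate projection, evaluation statistics
    (two-proportion z-test, motif-match ratios, a log-odds PWM scanner,
    VCF haplotype-compatibility analysis), and a synthetic-data
    generator producing variant graphs, haplotype panels and simulated
    ChIP/control alignments for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
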
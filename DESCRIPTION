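Package: provsel
Title: Retroviral Integration-Site Analysis with Matched Random Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of retroviral provirus integration sites relative to
    genome annotation: generation of restriction-site-matched random controls
    (umMRC) and active-gene-matched controls (agMRC), active-gene calling from
    H3K4me3 peak, Tss chromatin-segment and CAGE evidence, merging of
    ChromHMM-style chromatin segments into Active and Regulatory groups,
    nearest-feature distance and targeting-frequency summaries, and exact
    small-sample inference (two-sided Fisher test on 2x2 counts, exact
    Wilcoxon signed-rank on site-versus-control distances). A synthetic-data
    module simulates genomes, annotation tracks, integration cohorts with
    configurable gene-body, TSS-proximal, enhancer-proximal and orientation
    biases, and clonal GFP reporter silencing trajectories, so the complete
    pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    IRanges,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
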
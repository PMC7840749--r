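Package: boranekit
Title: Simulation, Calling and Joint Estimation for Borane-Reduction
    Cytosine-Modification Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational toolkit for the borane-reduction family of
    bisulfite-free cytosine-modification sequencing assays (TAPS, TAPSbeta,
    CAPS, PS, PS-c). Provides chemistry-aware paired-end read simulation
    with spike-in controls and ground truth, a strand-aware C-to-T
    modification caller over aligned reads, spike-in conversion-rate and
    false-positive quality control, binomial significance calling of
    5-hydroxymethylcytosine with false-discovery-rate control, constrained
    joint maximum-likelihood estimation of 5mC/5hmC proportions from assay
    combinations, and genome-interval statistics (binned signals, Pearson
    comparisons, regulatory-element enrichment with random background,
    peak-centred metaplots and CpG-island coverage profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
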
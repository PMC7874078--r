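Package: atacprofiler
Title: Genome-Wide Chromatin Accessibility Profiling from ATAC-Seq Fragments
Version: 0.1.0
Authors@R: person("ATAC", "Profiler Developers", email = "atacprofiler@example.org",
    role = c("aut", "cre"))
Description: A modular toolkit for profiling chromatin accessibility from
    aligned paired-end ATAC-seq data. Provides organelle and duplicate
    filtering, fragment-size distributions with FFT-based estimation of
    nucleosome periodicity, accessible-region detection with a Poisson
    local-background peak caller in full-fragment and integration-site modes,
    genomic-feature enrichment statistics, gene- and peak-anchored signal
    matrices (heatmaps and metaplots), IGV junction tracks, differential
    accessibility between sample groups (fold-change plus t-test, and a
    Gaussian-mixture outlier model for promoters), hypergeometric peak-overlap
    testing against other interval datasets, and integration with gene
    expression. Includes a deterministic synthetic-data generator so every
    analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite,
    mvtnorm,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
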
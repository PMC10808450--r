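Package: oscinfer
Title: Inference of Oscillatory Gene Expression from Unsynchronized
    Single-Cell RNA-Seq and Reporter Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects co-oscillating genes in unsynchronized single-cell
    RNA-seq expression matrices via a paired-sine distance over all gene
    pairs, permutation significance with Benjamini-Hochberg control, and
    modularity-based community extraction on the significant-pair network.
    Includes the upstream per-cluster gene filters (zero-filtering and
    variance-filtering), downstream gene-list algebra with hypergeometric
    overlap statistics and low-cycling cluster classification, a
    Lomb-Scargle periodicity pipeline for fluorescence reporter traces
    (Gaussian-weighted detrending, power spectral density, dominant
    period extraction, per-condition averaging), and a synthetic-data
    generator with planted oscillator groups and known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
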
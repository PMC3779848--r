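Package: centropy
Title: Cluster Entropy of Long-Range Correlated Sequences and DNA Walks
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Partitions a long-range correlated series, in particular the
    purine/pyrimidine walk of a nucleotide sequence, into clusters by the
    crossings of the series with its moving average; estimates the cluster
    length distribution and its Shannon (cluster) entropy, decomposed into an
    ordered logarithmic term D log(l) and a disordered linear term l/n;
    estimates the Hurst exponent by detrending-moving-average variance
    scaling; and quantifies per-cluster nucleotide composition fluctuations
    and their correlation with per-chromosome genomic features.  Includes
    exact circulant-embedding generators of fractional Gaussian noise and of
    synthetic DNA with prescribed base composition and Hurst exponent.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
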
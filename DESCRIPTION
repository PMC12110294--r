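Package: msscae
Title: Multiscale Simplicial Complex Approximate Entropy for Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the irregularity of one-dimensional time series
    (heart-rate-variability RR-interval records in particular) through the
    simplicial complex approximate entropy (SCAE): the series is delay-embedded
    into a point cloud, a Vietoris-Rips complex is built at a tolerance tied to
    the series' standard deviation, and the entropy is the negative log ratio of
    realized simplex fractions in consecutive dimensions. A composite multiscale
    extension (MS-SCAE) applies the entropy to coarse-grained subseries across
    scale factors. Sample-entropy-based multiscale baselines (MSE with
    non-overlapping windows, MMSE with moving averages), seeded generators for
    white and 1/f noise, shuffled surrogates, an RR-interval reader, and
    per-scale Mann-Whitney group comparisons round out the analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
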
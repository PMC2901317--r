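Package: maxrs
Title: Rank-Sum Probe Selection for Cross-Species Microarray Hybridization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for heterologous (cross-species) hybridization on
    multi-probe-per-transcript microarrays. Sequence divergence between the study
    species and the array's reference species depresses hybridization signal
    unevenly across the probes of a probe set; the MAXRS (maximum rank sum) method
    selects, for each probe set, the probe that consistently ranks highest across
    arrays and uses its intensity as the expression estimate. The package provides
    background filtering against no-probe spots, rank-sum probe selection with
    Friedman rank-consistency diagnostics, quantile normalization, empirical-Bayes
    moderated t-tests with Benjamini-Hochberg false discovery rate control, and a
    synthetic probe-level data generator with known ground truth so the whole
    pipeline is verifiable without real array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
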
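Package: splicestress
Title: Statistics for Infection-Induced Alternative Splicing Changes
Version: 0.1.0
Authors@R:
    person("Splicestress", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies stress- or infection-induced changes in alternative
    splicing from isoform-ratio and intron-retention data: Shannon-entropy
    isoform diversity shifts, a distance-based multivariate permutation test
    on isoform ratios, ratio-weighted effective feature lengths with a
    label-permutation/G-test null, Bayesian percent-spliced-in (PSI)
    comparison of intron retention with Savage-Dickey Bayes factors and
    cross-line recurrence, allele-frequency-matched positional and splicing
    enhancer enrichment nulls, and intron characterization (GC content,
    Pol II signal normalization, uORF overlap). A synthetic-data module
    generates all pipeline inputs with planted, parameterized effects so
    every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
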
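Package: satmut
Title: Library Size and Fitness-Loss Statistics for Saturation Mutagenesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Statistical design of saturation-mutagenesis experiments.
    Translates degenerate-codon randomization schemes (NNN, NNK, NNS, NNB,
    or explicit codon mixtures) into amino-acid probability distributions
    and variant-space sampling probabilities; computes library coverage
    metrics (expected coverage, probability of full coverage via
    class-based inclusion-exclusion, probability of discovering any of the
    top-k variants) and minimal library sizes; simulates protein fitness
    landscapes under three generative models (a four-parameter Gaussian
    random-effects model, the NK model, and the rough Mount Fuji model);
    estimates the expected fitness of the best variant discovered as a
    function of library size, the 95-percent-of-gap library size, and the
    distribution of percent fitness loss; and fits the Gaussian landscape
    model to variant fitness tables by maximum likelihood.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
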
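Package: rngbias
Title: Computational Models of Bias in Human Random Number Generation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequential multinomial softmax choice models of human random
    number generation (RNG) tasks: a repetition bias, a spatial distance
    bias on the response keypad, and a gambler's-fallacy "cycling" bias
    driven by the gap since each digit was last produced.  Provides
    history-dependent feature encoding, per-sequence maximum-likelihood and
    hierarchical Bayesian estimation with convergence diagnostics,
    model-driven sequence simulation and permutation baselines, four
    randomness measures (phi index, block entropy, coupon score, mean
    repetition gap), predictive-accuracy scoring with tie splitting,
    paired model comparison, bootstrap out-of-bag classification of
    sequence sources, and a parameter-recovery study, with a command-line
    interface binding all stages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
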
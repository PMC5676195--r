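Package: specgc
Title: Frequency-Domain Granger Causality for Vector Autoregressive Processes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Defines, simulates and estimates linear vector autoregressive
    (VAR) models and computes frequency-domain directed-influence measures
    for them: classical Geweke spectral Granger causality from separately
    fitted full and reduced models, a closed-form state-space estimator
    based on the innovations representation and a discrete algebraic
    Riccati equation, and directed coherence / partial directed coherence
    together with the causal decomposition of the receiver power spectrum.
    Includes the oscillator benchmark systems and Monte Carlo study runner
    used to compare estimator bias and variability, plus a small command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
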
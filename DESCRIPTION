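Package: crossrank
Title: Simulation-Based Selection of Cross Combinations in Self-Pollinated
    Crop Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of recurrent genomic selection schemes in
    self-pollinated crops, built around an in-silico progeny engine that
    ranks every pairwise cross of a genotyped population by the predicted
    trait values of its simulated F2 progeny. Includes a diploid genome and
    additive QTL model, meiosis under the Haldane (no-interference) mapping
    function, single-seed-descent inbreeding to recombinant inbred lines,
    L1-penalized (LASSO) marker-effect prediction models with
    cross-validated penalty choice, six benchmark parent-selection
    strategies (one, five or ten crosses chosen by simulated progeny values
    or by individual prediction values), a replicated multi-cycle scheme
    runner with matched-pair comparison statistics, and plain-text
    interchange formats plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
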
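Package: suctionmorph
Title: Suction-Feeding Specialization Indices and Phylogenetic Tests of
    Ecomorphological Convergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies morphological specialization for suction feeding in
    toothed whales (odontocetes) from ordinal character scores. Computes the
    suction specialization index (SSI) and its fossil-ready adjusted variant,
    tests association between character scores and prey-capture mode with
    Kruskal-Wallis tests, Blomberg's K phylogenetic signal, and phylogenetic
    generalized least squares under Brownian motion, evaluates single- and
    multi-character logistic classifiers against the no-information rate with
    exact binomial inference, and tests for convergence in skull-shape
    morphospace with Stayton's C1 metric under a Brownian-motion simulation
    null. Includes a synthetic-data generator (Yule trees, threshold-model
    ordinal characters with planted specialist clades) so the full pipeline
    is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    phytools,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme
Config/testthat/edition: 3
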
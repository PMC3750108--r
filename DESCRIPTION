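Package: plpath
Title: Projection to Latent Pathways for Elementary Flux Mode Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates the subset of elementary flux modes (EFM) of a
    metabolic network that is best correlated with measured environmental
    ("envirome") data, using projection to latent pathways (PLP): a
    constrained partial least squares (PLS) regression in which the response
    loadings are fixed to candidate EFM and their weighting factors are
    regressed on the envirome by inner univariate NIPALS-PLS models.
    Includes the NIPALS-PLS core, an exact-arithmetic tableau enumerator of
    elementary flux modes for small networks, Metatool-style network input,
    a bootstrap over random calibration/validation partitions yielding EFM
    selection frequencies and regression-coefficient intervals, and a
    synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    mixOmics
Config/testthat/edition: 3
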
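Package: aesim
Title: Monte Carlo Comparison of Autoencoders and Principal Component
    Analysis for Psychometric Construct Validity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how well dimension-reduction methods recover
    the latent structure of multi-item questionnaires when samples are small
    and responses are non-normal. Provides a generator of correlated
    multivariate non-normal data with controlled communality, skewness and
    kurtosis (Fleishman cubic transforms combined with Vale-Maurelli
    intermediate correlations and Kaiser-Dickman factor-pattern imposition);
    five dimension reducers under a common fit/encode/reconstruct contract
    (principal component analysis and four autoencoder variants: simple,
    tied-weight, deep, and covariance/orthogonality-penalized); reconstruction
    error metrics (MSE, MAE, and a sign-based normalized Euclidean distance);
    a factorial Monte Carlo experiment driver with tidy summaries; and an
    item-to-construct assignment procedure based on bottleneck weights.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
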
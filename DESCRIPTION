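Package: nbsig
Title: Mutational Signature Extraction with Negative Binomial NMF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction of mutational signatures from SBS96 count matrices by
    non-negative matrix factorization under a Negative Binomial model with
    patient-specific dispersion, fitted by majorization-minimization
    multiplicative updates. Includes maximum likelihood estimation of the
    dispersion parameters, a cross-validation-style procedure (SigMoS) for
    choosing the number of signatures, classical AIC/BIC selection,
    residual-based model diagnostics, cosine-similarity matching against
    signature catalogs, and a simulation generator for overdispersed
    mutational count data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    graphics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
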
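Package: lsproj
Title: Privacy-Preserving Obfuscation by Latent Space Projection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements latent space projection (LSP), a privacy-preserving
    obfuscation method in which an adversarially trained autoencoder splits
    its latent space into a sensitive subspace and a nonsensitive subspace,
    so that data can be released with the sensitive subspace neutralised.
    Provides the adversarial training procedure (reconstruction objective,
    sensitive-routing head, privacy discriminator), a post-hoc evaluation
    harness (attribute-inference and model-inversion attacks, protection
    score, downstream utility, PSNR/SSIM image fidelity, fairness gaps),
    comparison baselines (Mondrian k-anonymity, k-Same image averaging,
    the Gaussian mechanism of differential privacy), seeded synthetic image
    and transaction-table generators, and a benchmark harness that assembles
    privacy-utility comparison tables and curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    png,
    glmnet,
    xgboost,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
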
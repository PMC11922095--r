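# Shared fixtures. Heavy artefacts (trained models at the study sizes) are
# memoised so several tests can reuse one training run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# tiny architectures for fast structural / numeric tests
tiny_image_spec <- function(d_s = 2L, ...) {
  lsp_spec("image", c(16L, 16L, 1L), latent_dim = 8L, d_s = d_s,
           conv_filters = c(4L, 6L, 8L, 10L),
           discriminator_widths = c(16L, 12L, 8L), ...)
}

tiny_image_data <- function(n = 64L, seed = 1L, ...) {
  generate_images(image_gen_config(n_samples = n, image_size = 16L,
                                   seed = seed, ...))
}

tiny_tab_data <- function(n = 400L, seed = 1L, ...) {
  generate_transactions(tabular_gen_config(
    n_samples = n, n_features = 8L, fraud_rate = 0.3, sensitive_rate = 0.4,
    fraud_coefs = c(2, 2, 0, 0, 0, 0, 0, 0),
    sensitive_coefs = c(0, 0, 2.5, 2.5, 0, 0, 0, 0), seed = seed, ...))
}

# one small trained image model shared across interface tests
tiny_fit <- function() {
  memo("tiny_fit",
       lsp(tiny_image_data(48, seed = 3), gamma = 0.2, epochs = 2,
           batch_size = 16, spec = tiny_image_spec(), seed = 1))
}

# the image study conditions: 2000 32x32 images, uncorrelated label and
# sensitive attribute, seed 7, 20 training epochs
study_image_data <- function() {
  memo("study_image_data",
       generate_images(image_gen_config(n_samples = 2000L,
                                        label_attr_correlation = 0,
                                        seed = 7L)))
}

study_image_run <- function(gamma) {
  memo(paste0("study_image_run_", gamma),
       lsp(study_image_data(), gamma = gamma, epochs = 20L, seed = 7L))
}

# tabular study for the privacy-weight sweep: imbalance kept mild so the
# attack signal is informative, sensitive attribute driven by 2 of 12
# features
sweep_tab_data <- function(seed) {
  generate_transactions(tabular_gen_config(
    n_samples = 4000L, n_features = 12L, fraud_rate = 0.25,
    sensitive_rate = 0.4,
    fraud_coefs = c(rep(1.5, 4), rep(0, 8)),
    sensitive_coefs = c(rep(0, 4), 3, 3, rep(0, 6)),
    seed = seed))
}

sweep_tab_attack_acc <- function(gamma, seed) {
  memo(paste0("sweep_tab_", gamma, "_", seed), {
    d <- sweep_tab_data(seed)
    fit <- lsp(d, gamma = gamma, epochs = 20L, seed = seed)
    zns <- predict(fit, d, type = "z_ns")
    att <- attribute_inference_attack(zns, d$s,
                                      config = attack_config(epochs = 20L),
                                      seed = seed)
    list(accuracy = att$report$attack_accuracy,
         protection = att$report$protection_pct,
         history = fit$history)
  })
}

expect_seeded_identical <- function(expr1, expr2) {
  expect_identical(expr1, expr2)
}
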
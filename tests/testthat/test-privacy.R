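# Protection score algebra, attribute-inference attack behaviour on
# constructed leakage extremes, and the model-inversion attack.

test_that("protection score endpoints and monotonicity", {
  expect_equal(protection_score(0.5, 0.5), 100)
  expect_equal(protection_score(1, 0.5), 0)
  expect_equal(protection_score(0.55, 0.5), 90)
  # below-chance attacks are clamped at 100
  expect_equal(protection_score(0.3, 0.5), 100)
  # monotone non-increasing in attack accuracy for fixed chance
  for (c_rate in c(0.5, 0.7, 0.9)) {
    accs <- seq(0, 1, by = 0.05)
    ps <- protection_score(accs, c_rate)
    expect_true(all(diff(ps) <= 1e-12))
  }
  expect_error(protection_score(0.5, 1), "\\[0, 1\\)")
})

test_that("latents that contain s explicitly are fully attackable", {
  set.seed(31)
  n <- 600
  s <- rbinom(n, 1, 0.5)
  latents <- cbind(s, matrix(rnorm(n * 7), n, 7))
  res <- attribute_inference_attack(latents, s,
                                    config = attack_config(epochs = 12),
                                    seed = 3)
  expect_gte(res$report$attack_accuracy, 0.99)
  expect_lte(res$report$protection_pct, 2)
})

test_that("latents independent of s are unattackable", {
  set.seed(32)
  n <- 800
  s <- rbinom(n, 1, 0.5)
  latents <- matrix(rnorm(n * 10), n, 10)
  res <- attribute_inference_attack(latents, s,
                                    config = attack_config(epochs = 12),
                                    seed = 5)
  expect_lt(abs(res$report$attack_accuracy - res$report$chance_rate), 0.05)
  expect_gte(res$report$protection_pct, 90)
})

test_that("attack reports are deterministic, split-disjoint and brute-force consistent", {
  set.seed(33)
  n <- 300
  s <- rbinom(n, 1, 0.4)
  latents <- cbind(s + rnorm(n, sd = 0.8), matrix(rnorm(n * 4), n, 4))
  r1 <- attribute_inference_attack(latents, s,
                                   config = attack_config(epochs = 8), seed = 9)
  r2 <- attribute_inference_attack(latents, s,
                                   config = attack_config(epochs = 8), seed = 9)
  expect_identical(r1$report, r2$report)

  # brute-force recomputation of held-out accuracy from the attacker itself
  ns <- asNamespace("lsproj")
  idx <- ns$with_seed(9, sample.int(n))
  te <- idx[(floor(n * 0.7) + 1L):n]
  pred <- ns$predict_attacker(r1$attacker, t(latents)[, te, drop = FALSE])
  hits <- 0
  for (i in seq_along(te)) if (pred[i] == s[te[i]]) hits <- hits + 1
  expect_equal(r1$report$attack_accuracy, hits / length(te))
  expect_equal(r1$report$n_eval, length(te))
  # attacker never trains on evaluation samples: splits are disjoint
  expect_length(intersect(idx[seq_len(floor(n * 0.7))], te), 0)

  expect_error(attribute_inference_attack(latents, rep(1, n)),
               "single class")
})

test_that("model inversion succeeds against an identity release", {
  d <- generate_images(image_gen_config(n_samples = 240, image_size = 16,
                                        noise_sd = 0.02, seed = 14))
  pub <- dataset_subset(d, 1:160)
  priv <- dataset_subset(d, 161:240)
  identity_release <- function(x) x
  rep1 <- model_inversion_attack(identity_release, pub, priv, tau = 0.8,
                                 seed = 1)
  expect_gte(rep1$success_rate, 0.95)
  # impossible threshold
  rep2 <- model_inversion_attack(identity_release, pub, priv, tau = 1 + 1e-9)
  expect_equal(rep2$success_rate, 0)
  # determinism
  rep3 <- model_inversion_attack(identity_release, pub, priv, tau = 0.8,
                                 seed = 1)
  expect_identical(rep1, rep3)
  expect_error(model_inversion_attack(identity_release, tiny_tab_data(20),
                                      tiny_tab_data(20)),
               "image modality")
})

test_that("model inversion runs against a trained LSP model", {
  d <- tiny_image_data(60, seed = 9)
  fit <- tiny_fit()
  rep <- model_inversion_attack(fit, dataset_subset(d, 1:40),
                                dataset_subset(d, 41:60), seed = 2)
  expect_true(rep$success_rate >= 0 && rep$success_rate <= 1)
  expect_length(rep$similarity, 20)
  expect_true(all(is.finite(rep$similarity)))
})
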
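# Synthetic image and transaction generators: determinism, marginal rates,
# label/attribute coupling, and the train/test split contract.

test_that("generators are bit-identical under a fixed seed", {
  c1 <- image_gen_config(n_samples = 50, sensitive_rate = 0.5, seed = 7)
  expect_identical(generate_images(c1), generate_images(c1))
  c2 <- tabular_gen_config(n_samples = 500, n_features = 6,
                           fraud_rate = 0.2, seed = 7,
                           fraud_coefs = rep(1, 6), sensitive_coefs = rep(1, 6))
  expect_identical(generate_transactions(c2), generate_transactions(c2))
})

test_that("image pixels stay in [0,1] and marginal rates follow binomial bounds", {
  d <- generate_images(image_gen_config(n_samples = 10000, image_size = 8,
                                        sensitive_rate = 0.3, noise_sd = 0.2,
                                        seed = 3))
  expect_true(all(d$x >= 0 & d$x <= 1))
  # central 99% binomial interval for the sensitive rate
  lo <- qbinom(0.005, 10000, 0.3)
  hi <- qbinom(0.995, 10000, 0.3)
  expect_gte(sum(d$s), lo)
  expect_lte(sum(d$s), hi)
})

test_that("label/attribute phi correlation is controlled", {
  d0 <- generate_images(image_gen_config(n_samples = 4000, image_size = 8,
                                         label_attr_correlation = 0, seed = 5))
  phi <- function(y, s) {
    suppressWarnings(stats::cor(y, s))
  }
  expect_lt(abs(phi(d0$y, d0$s)), 3 / sqrt(4000))
  d5 <- generate_images(image_gen_config(n_samples = 4000, image_size = 8,
                                         label_attr_correlation = 0.5, seed = 5))
  expect_lt(abs(phi(d5$y, d5$s) - 0.5), 0.05)
})

test_that("infeasible correlation requests are rejected with the feasible interval", {
  err <- expect_error(
    image_gen_config(class_rate = 0.9, sensitive_rate = 0.1,
                     label_attr_correlation = 0.9),
    "feasible interval")
  expect_match(conditionMessage(err), "\\[")
})

test_that("a linear probe recovers both factors from raw pixels", {
  d <- generate_images(image_gen_config(n_samples = 2000,
                                        label_attr_correlation = 0,
                                        noise_sd = 0.05, seed = 11))
  half <- seq_len(1000)
  for (target in c("y", "s")) {
    lab <- d[[target]]
    fit <- glmnet::glmnet(d$x[half, ], factor(lab[half]), family = "binomial",
                          alpha = 0, lambda = 0.05)
    p <- as.numeric(predict(fit, d$x[-half, ], type = "response"))
    expect_gte(mean((p > 0.5) == lab[-half]), 0.90)
  }
})

test_that("transaction prevalence is calibrated to the configured rate", {
  d <- generate_transactions(tabular_gen_config(n_samples = 100000, seed = 2))
  # 0.172% prevalence: positive count within the exact central 99% interval
  expect_gte(sum(d$y), qbinom(0.005, 100000, 0.00172))
  expect_lte(sum(d$y), qbinom(0.995, 100000, 0.00172))
})

test_that("zero fraud coefficients leave features independent of the label", {
  d <- generate_transactions(tabular_gen_config(
    n_samples = 50000, n_features = 4, fraud_rate = 0.3,
    fraud_coefs = rep(0, 4), sensitive_coefs = rep(1, 4), seed = 9))
  for (j in 1:4) expect_lt(abs(cor(d$x[, j], d$y)), 0.02)
})

test_that("coefficient length mismatches are rejected", {
  expect_error(tabular_gen_config(n_features = 5, fraud_coefs = rep(1, 3)),
               "length n_features")
})

test_that("train_test_split uses the floor rule and partitions exactly", {
  d <- generate_images(image_gen_config(n_samples = 2637, image_size = 8,
                                        seed = 1))
  sp <- train_test_split(d, 0.8, seed = 1)
  expect_equal(length(sp$train), 2109)
  expect_equal(length(sp$test), 528)

  d10 <- dataset_subset(d, 1:10)
  sp10 <- train_test_split(d10, 0.5, seed = 2)
  expect_equal(length(sp10$train), 5)
  expect_equal(length(sp10$test), 5)
  joined <- rbind(sp10$train$x, sp10$test$x)
  expect_equal(dim(joined), dim(d10$x))
  # disjoint and exhaustive: every original row appears exactly once
  key <- function(m) apply(m, 1, function(r) paste(signif(r, 12), collapse = ","))
  expect_setequal(key(joined), key(d10$x))
  expect_equal(anyDuplicated(key(joined)), 0)

  d101 <- dataset_subset(d, 1:101)
  sp101 <- train_test_split(d101, 0.8, seed = 3)
  expect_equal(length(sp101$train), 80)
  expect_equal(length(sp101$test), 21)

  expect_error(train_test_split(dataset_subset(d, 1), 0.5), "at least 2")
})
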
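# Losses against closed forms and brute force, seeded reproducibility,
# the degenerate autoencoder limit, freeze discipline, and latent statistics.

test_that("reconstruction loss matches closed forms and brute force", {
  x <- matrix(runif(50), 10, 5)
  expect_identical(reconstruction_loss(x, x), 0)
  expect_equal(reconstruction_loss(x, x + 0.1), 0.01, tolerance = 1e-12)
  y <- matrix(runif(50), 10, 5)
  brute <- 0
  for (i in seq_along(x)) brute <- brute + (x[i] - y[i])^2
  expect_equal(reconstruction_loss(x, y), brute / length(x), tolerance = 1e-12)
  expect_error(reconstruction_loss(x, matrix(0, 5, 10)), "identical shapes")
})

test_that("privacy loss is the mean cross-entropy", {
  s <- c(1, 0, 1, 1)
  expect_lte(privacy_loss(c(1, 0, 1, 1), s), 1e-6)
  expect_equal(privacy_loss(rep(0.5, 4), s), log(2), tolerance = 1e-12)
  p <- runif(4, 0.05, 0.95)
  brute <- mean(-(s * log(p) + (1 - s) * log(1 - p)))
  expect_equal(privacy_loss(p, s), brute, tolerance = 1e-12)
  # categorical head
  pm <- matrix(c(0.7, 0.2, 0.1,
                 0.1, 0.8, 0.1), 2, 3, byrow = TRUE)
  sc <- c(1, 2)
  expect_equal(privacy_loss(pm, sc), mean(-log(c(0.7, 0.8))), tolerance = 1e-12)
  expect_error(privacy_loss(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("training is bit-reproducible under a fixed seed", {
  d <- tiny_tab_data(300, seed = 5)
  f1 <- lsp(d, gamma = 0.5, epochs = 3, batch_size = 32, seed = 11)
  f2 <- lsp(d, gamma = 0.5, epochs = 3, batch_size = 32, seed = 11)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$encoder, f2$encoder)
  f3 <- lsp(d, gamma = 0.5, epochs = 3, batch_size = 32, seed = 12)
  expect_false(identical(f3$history, f1$history))
})

test_that("gamma = 0, lambda_s = 0 reduces to plain autoencoder training", {
  ns <- asNamespace("lsproj")
  d <- tiny_image_data(32, seed = 6)
  spec <- tiny_image_spec()
  seed <- 21L
  model <- list(encoder = build_encoder(spec, seed),
                decoder = build_decoder(spec, seed + 1L),
                aux = NULL, spec = spec)
  disc <- build_discriminator(spec, seed + 2L)
  cfg <- lsp_train_config(gamma = 0, lambda_s = 0, epochs = 1,
                          batch_size = 32, seed = seed)
  tr <- train_lsp(model, disc, d, cfg)

  # reference: one reconstruction-only Adam step computed from primitives
  enc <- ns$net_clone_params(model$encoder)
  dec <- ns$net_clone_params(model$decoder)
  set.seed(seed)
  perm <- sample.int(32)
  Xb <- t(d$x)[, perm, drop = FALSE]
  fe <- ns$nn_forward(enc, Xb, training = TRUE)
  enc <- fe$net
  fd <- ns$nn_forward(dec, fe$out, training = TRUE)
  dec <- fd$net
  bdec <- ns$nn_backward(dec, fd$caches, 2 * (fd$out - Xb) / length(fd$out))
  benc <- ns$nn_backward(enc, fe$caches, bdec$dX)
  ns$adam_step(enc, ns$adam_state(enc), benc$grads, cfg$learning_rate, 1)
  ns$adam_step(dec, ns$adam_state(dec), bdec$grads, cfg$learning_rate, 1)
  expect_equal(tr$model$encoder$layers[[2]]$params$W,
               enc$layers[[2]]$params$W, tolerance = 1e-12)
  expect_equal(tr$model$decoder$layers[[1]]$params$W,
               dec$layers[[1]]$params$W, tolerance = 1e-12)
})

test_that("adversarial steps never touch the frozen network's parameters", {
  ns <- asNamespace("lsproj")
  d <- tiny_image_data(32, seed = 8)
  spec <- tiny_image_spec()
  model <- list(encoder = build_encoder(spec, 1),
                decoder = build_decoder(spec, 2),
                aux = ns$build_aux_head(spec, 4), spec = spec)
  disc <- build_discriminator(spec, 3)
  enc_hash0 <- ns$nn_param_hash(model$encoder)
  disc_hash0 <- ns$nn_param_hash(disc)
  tr <- train_lsp(model, disc, d,
                  lsp_train_config(gamma = 1, epochs = 1, batch_size = 32,
                                   seed = 1))
  # the caller's objects are untouched (training clones parameters) ...
  expect_identical(ns$nn_param_hash(model$encoder), enc_hash0)
  expect_identical(ns$nn_param_hash(disc), disc_hash0)
  # ... while the returned networks moved
  expect_false(isTRUE(all.equal(ns$nn_param_hash(tr$model$encoder), enc_hash0)))
  expect_false(isTRUE(all.equal(ns$nn_param_hash(tr$discriminator), disc_hash0)))
})

test_that("history is complete and finite; invalid configs are rejected", {
  d <- tiny_tab_data(200, seed = 2)
  fit <- lsp(d, gamma = 0.2, epochs = 4, batch_size = 50, seed = 3)
  h <- fit$history
  expect_equal(nrow(h), 4L)
  expect_true(all(is.finite(as.matrix(h))))
  expect_error(lsp_train_config(gamma = -1), "gamma")
  expect_error(lsp_train_config(epochs = 0))
})

test_that("latent statistics match brute-force averages and respect the cap", {
  d <- tiny_image_data(40, seed = 4)
  fit <- tiny_fit()
  st <- fit_latent_statistics(fit, d, cap = 16, seed = 2)
  zs <- split_latent(encode(fit, d))$z_s
  expect_equal(st$mean_z_s, colMeans(zs), tolerance = 1e-12)
  expect_lte(nrow(st$bank), 16)

  # constant dataset: stored mean equals the single z_s value
  dc <- d
  dc$x <- matrix(rep(d$x[1, ], 5), 5, ncol(d$x), byrow = TRUE)
  dc$y <- d$y[1:5]; dc$s <- d$s[1:5]
  stc <- fit_latent_statistics(fit, dc)
  z1 <- split_latent(encode(fit, dc))$z_s[1, ]
  expect_equal(stc$mean_z_s, z1, tolerance = 1e-12)
  expect_error(fit_latent_statistics(fit, dataset_subset(d, integer(0))),
               "empty")
})
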
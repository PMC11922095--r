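# Architecture contracts: shapes, seeded initialisation, the latent split,
# parameter counts against a closed-form oracle, and obfuscation semantics.

test_that("image encoder maps 32x32 inputs to a 128-vector, batched and pure", {
  spec <- lsp_spec("image", c(32, 32, 1))
  enc <- build_encoder(spec, seed = 1)
  model <- list(encoder = enc, spec = spec)
  x <- matrix(runif(16 * 1024), 16, 1024)
  z <- encode(model, x)
  expect_equal(dim(z$z), c(16L, 128L))
  expect_identical(encode(model, x)$z, z$z)            # eval-mode purity
  perm <- c(5:16, 1:4)
  expect_identical(encode(model, x[perm, ])$z, z$z[perm, ])  # order equivariance
})

test_that("tabular encoder has exactly 3 weight layers ending at latent 64", {
  spec <- lsp_spec("tabular", 30)
  enc <- build_encoder(spec, seed = 2)
  weighted <- vapply(enc$layers, function(l)
    l$type %in% c("dense", "conv", "tconv"), TRUE)
  expect_equal(sum(weighted), 3L)
  x <- matrix(rnorm(5 * 30), 5, 30)
  expect_equal(dim(encode(list(encoder = enc, spec = spec), x)$z), c(5L, 64L))
})

test_that("same spec and seed give identical initial parameters", {
  spec <- lsp_spec("image", c(32, 32, 1))
  e1 <- build_encoder(spec, seed = 42)
  e2 <- build_encoder(spec, seed = 42)
  expect_identical(e1, e2)
  e3 <- build_encoder(spec, seed = 43)
  expect_false(identical(e1$layers[[2]]$params$W, e3$layers[[2]]$params$W))
})

test_that("decoder mirrors the input shape and respects the [0,1] pixel contract", {
  spec <- lsp_spec("image", c(32, 32, 1))
  model <- list(encoder = build_encoder(spec, 1),
                decoder = build_decoder(spec, 2), spec = spec)
  z <- matrix(rnorm(8 * 128, sd = 3), 8, 128)
  out <- decode(model, z)
  expect_equal(dim(out), c(8L, 1024L))
  expect_true(all(out >= 0 & out <= 1))
  # untrained round-trip error is finite and positive
  x <- matrix(runif(4 * 1024), 4, 1024)
  err <- reconstruction_loss(x, decode(model, encode(model, x)))
  expect_true(is.finite(err))
  expect_gt(err, 0)
})

test_that("non-divisible image sizes are rejected with resize guidance", {
  expect_error(lsp_spec("image", c(30, 30, 1)), "pad or resize")
})

test_that("latent split is a lossless fixed-index partition", {
  z <- structure(list(z = matrix(rnorm(3 * 128), 3, 128), d_s = 16L,
                      d_ns = 112L), class = "lsp_latent")
  sp <- split_latent(z)
  expect_equal(ncol(sp$z_s), 16L)
  expect_equal(ncol(sp$z_ns), 112L)
  expect_identical(cbind(sp$z_s, sp$z_ns), z$z)
  z1 <- structure(list(z = matrix(rnorm(2 * 8), 2, 8), d_s = 1L, d_ns = 7L),
                  class = "lsp_latent")
  expect_equal(ncol(split_latent(z1)$z_s), 1L)
})

test_that("discriminator heads are probabilistic and eval-deterministic", {
  spec2 <- lsp_spec("tabular", 10, latent_dim = 16, d_s = 2)
  d2 <- build_discriminator(spec2, seed = 1)
  x <- matrix(rnorm(6 * 14), 14, 6)
  p <- lsproj:::nn_forward(d2, x, training = FALSE)$out
  expect_true(all(p > 0 & p < 1))
  expect_equal(dim(p), c(1L, 6L))
  expect_identical(lsproj:::nn_forward(d2, x, training = FALSE)$out, p)

  spec4 <- lsp_spec("tabular", 10, latent_dim = 16, d_s = 2,
                    sensitive_cardinality = 4)
  d4 <- build_discriminator(spec4, seed = 1)
  p4 <- lsproj:::nn_forward(d4, x, training = FALSE)$out
  expect_equal(nrow(p4), 4L)
  expect_equal(colSums(p4), rep(1, 6))

  expect_error(lsp_spec("tabular", 10, sensitive_cardinality = 1),
               "at least 2")
})

test_that("parameter counts match the closed-form layer arithmetic", {
  # image encoder: 4 conv blocks (32,64,128,256 filters, 3x3 kernels,
  # batch norm) + dense to latent 128
  spec <- lsp_spec("image", c(32, 32, 1))
  f <- c(32, 64, 128, 256)
  cin <- c(1, 32, 64, 128)
  conv_p <- sum(f * (9 * cin) + f)       # weights + biases
  bn_p <- sum(2 * f)                     # gamma + beta
  dense_p <- 128 * (2 * 2 * 256) + 128
  expect_equal(count_params(build_encoder(spec, 1)), conv_p + bn_p + dense_p)

  # tabular encoder: dense 28->256->128->64 with bn on hidden layers
  spect <- lsp_spec("tabular", 28)
  enc_t <- 256 * 28 + 256 + 2 * 256 + 128 * 256 + 128 + 2 * 128 + 64 * 128 + 64
  expect_equal(count_params(build_encoder(spect, 1)), enc_t)

  # discriminator: 112 -> 512 -> 256 -> 128 -> 1 with bn on hidden layers
  disc_p <- 512 * 112 + 512 + 2 * 512 +
    256 * 512 + 256 + 2 * 256 +
    128 * 256 + 128 + 2 * 128 +
    1 * 128 + 1
  expect_equal(count_params(build_discriminator(spec, 1)), disc_p)
  widths <- vapply(Filter(function(l) l$type == "dense",
                          build_discriminator(spec, 1)$layers),
                   function(l) nrow(l$params$W), 0L)
  expect_equal(widths, c(512L, 256L, 128L, 1L))
  drops <- Filter(function(l) l$type == "dropout",
                  build_discriminator(spec, 1)$layers)
  expect_equal(length(drops), 3L)
  expect_equal(unique(vapply(drops, function(l) l$rate, 0)), 0.3)

  # image encoder weight-layer count: 4 conv + 1 fully connected
  wl <- vapply(build_encoder(spec, 1)$layers, function(l)
    l$type %in% c("dense", "conv", "tconv"), TRUE)
  expect_equal(sum(wl), 5L)
})

test_that("network gradients match finite differences on a tiny model", {
  ns <- asNamespace("lsproj")
  spec <- lsp_spec("image", c(16, 16, 1), latent_dim = 8, d_s = 2,
                   conv_filters = c(4, 6, 8, 10))
  enc <- build_encoder(spec, 1)
  dec <- build_decoder(spec, 2)
  set.seed(99)
  X <- matrix(runif(256 * 3), 256, 3)
  tgt <- matrix(runif(256 * 3), 256, 3)
  loss_fn <- function(enc, dec) {
    fe <- ns$nn_forward(enc, X, training = TRUE)
    fd <- ns$nn_forward(dec, fe$out, training = TRUE)
    mean((fd$out - tgt)^2)
  }
  fe <- ns$nn_forward(enc, X, training = TRUE)
  fd <- ns$nn_forward(dec, fe$out, training = TRUE)
  bdec <- ns$nn_backward(dec, fd$caches, 2 * (fd$out - tgt) / length(fd$out))
  benc <- ns$nn_backward(enc, fe$caches, bdec$dX)
  eps <- 1e-6
  for (case in list(list(net = "enc", grads = benc$grads),
                    list(net = "dec", grads = bdec$grads))) {
    net <- if (case$net == "enc") enc else dec
    for (li in seq_along(net$layers)) {
      ps <- net$layers[[li]]$params
      if (!length(ps)) next
      for (nm in names(ps)) {
        i <- ((li * 7L) %% length(ps[[nm]])) + 1L   # deterministic element
        n2 <- net
        n2$layers[[li]]$params[[nm]][i] <- ps[[nm]][i] + eps
        lp <- if (case$net == "enc") loss_fn(n2, dec) else loss_fn(enc, n2)
        n2$layers[[li]]$params[[nm]][i] <- ps[[nm]][i] - eps
        lm <- if (case$net == "enc") loss_fn(n2, dec) else loss_fn(enc, n2)
        expect_equal(case$grads[[li]][[nm]][i], (lp - lm) / (2 * eps),
                     tolerance = 1e-4)
      }
    }
  }
})

test_that("obfuscation replaces z_s as requested", {
  d <- tiny_image_data(48, seed = 3)
  fit <- tiny_fit()
  o1 <- obfuscate(fit, d, mode = "zero")
  expect_identical(obfuscate(fit, d, mode = "zero"), o1)
  expect_equal(dim(o1), dim(d$x))
  om <- obfuscate(fit, d, mode = "mean")
  ors <- obfuscate(fit, d, mode = "resample", seed = 4)
  expect_false(identical(o1, om))
  expect_identical(obfuscate(fit, d, mode = "resample", seed = 4), ors)

  # without fitted statistics, mean/resample are refused
  bare <- fit
  bare$latent_stats <- NULL
  expect_error(obfuscate(bare, d, mode = "mean"), "latent statistics")

  # d_s = 0 degenerates to the plain autoencoder round trip
  spec0 <- tiny_image_spec(d_s = 0)
  m0 <- list(encoder = build_encoder(spec0, 5),
             decoder = build_decoder(spec0, 6), spec = spec0,
             latent_stats = NULL)
  expect_identical(obfuscate(m0, d, mode = "zero"),
                   decode(m0, encode(m0, d)))
})
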
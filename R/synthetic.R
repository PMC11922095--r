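# Seeded synthetic datasets with controlled coupling between features, the
# utility label y and the sensitive attribute s.
#
# Images emulate small grayscale tissue micrographs: the utility class is a
# morphological property of a central "lesion" (round blob vs elongated
# ellipse) while the sensitive attribute is an independent background texture
# property (horizontal vs vertical striping). Because shape and texture are
# geometrically independent, a representation can in principle retain one
# while discarding the other -- which is exactly the claim the LSP latent
# split is supposed to make testable.
#
# Tables emulate heavily imbalanced transaction data: standardized
# Gaussian-mixture features, a rare fraud label from a logistic model with a
# calibrated intercept, and a sensitive attribute driven by a (possibly
# overlapping) subset of the same features.

## ---- joint (y, s) sampling --------------------------------------------------

# 2x2 joint distribution with marginals py, ps and phi correlation `phi`.
# Returns the four cell probabilities or errors with the feasible interval.
.joint_bernoulli <- function(py, ps, phi) {
  denom <- sqrt(py * (1 - py) * ps * (1 - ps))
  p11 <- py * ps + phi * denom
  lo <- max(0, py + ps - 1)
  hi <- min(py, ps)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    if (denom == 0) stop("correlation must be 0 when a rate is 0 or 1")
    stop(sprintf(
      "label_attr_correlation %.4f is infeasible for rates (%.3f, %.3f); feasible interval is [%.4f, %.4f]",
      phi, py, ps, (lo - py * ps) / denom, (hi - py * ps) / denom))
  }
  p11 <- min(max(p11, lo), hi)
  c(p00 = 1 - py - ps + p11, p01 = ps - p11, p10 = py - p11, p11 = p11)
}

.sample_ys <- function(n, py, ps, phi) {
  p <- .joint_bernoulli(py, ps, phi)
  cell <- sample.int(4L, n, replace = TRUE, prob = p)
  list(y = as.integer(cell %in% c(3L, 4L)), s = as.integer(cell %in% c(2L, 4L)))
}

## ---- dataset container ------------------------------------------------------

new_dataset <- function(x, y, s, modality, image_size = NULL, channels = 1L) {
  stopifnot(nrow(x) == length(y), length(y) == length(s), !anyNA(x))
  structure(list(x = x, y = as.integer(y), s = as.integer(s),
                 modality = modality, image_size = image_size,
                 channels = as.integer(channels)),
            class = "lsp_dataset")
}

#' @export
print.lsp_dataset <- function(x, ...) {
  cat("lsp_dataset: ", nrow(x$x), " ", x$modality, " samples",
      if (x$modality == "image")
        paste0(" (", x$image_size, "x", x$image_size, ")"), "\n", sep = "")
  cat("  utility label rate  : ", round(mean(x$y), 4), "\n", sep = "")
  cat("  sensitive attr rate : ", round(mean(x$s), 4), "\n", sep = "")
  invisible(x)
}

#' @export
length.lsp_dataset <- function(x) nrow(x$x)

#' Subset a dataset by sample index
#' @param data an `lsp_dataset`.
#' @param idx integer indices of the samples to keep.
#' @return an `lsp_dataset` with the selected samples, order preserved.
#' @export
dataset_subset <- function(data, idx) {
  new_dataset(data$x[idx, , drop = FALSE], data$y[idx], data$s[idx],
              data$modality, data$image_size, data$channels)
}

## ---- image generator --------------------------------------------------------

#' Configuration for the synthetic image generator
#'
#' @param n_samples number of images.
#' @param image_size pixels per side (square, single channel); at least 8.
#' @param class_rate probability of the positive utility class.
#' @param sensitive_rate probability of sensitive attribute 1.
#' @param label_attr_correlation target phi correlation between label and
#'   sensitive attribute; must be feasible for the two rates.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed integer RNG seed.
#' @return a list of class `image_gen_config`.
#' @export
image_gen_config <- function(n_samples = 2000L, image_size = 32L,
                             class_rate = 0.5, sensitive_rate = 0.5,
                             label_attr_correlation = 0, noise_sd = 0.05,
                             seed = 1L) {
  stopifnot(n_samples >= 1L, image_size >= 8L,
            class_rate >= 0, class_rate <= 1,
            sensitive_rate >= 0, sensitive_rate <= 1,
            abs(label_attr_correlation) <= 1, noise_sd >= 0)
  .joint_bernoulli(class_rate, sensitive_rate, label_attr_correlation)
  structure(list(n_samples = as.integer(n_samples),
                 image_size = as.integer(image_size),
                 class_rate = class_rate, sensitive_rate = sensitive_rate,
                 label_attr_correlation = label_attr_correlation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "image_gen_config")
}

# One clean image: striped background plus a central lesion.
# y = 0 -> circular blob; y = 1 -> elongated ellipse at 45 degrees.
# s = 0 -> horizontal stripes; s = 1 -> vertical stripes.
.draw_image <- function(size, y, s, stripe_freq = 4, stripe_amp = 0.12,
                        base = 0.45, lesion_gain = 0.3) {
  ctr <- (size + 1) / 2
  gy <- matrix(seq_len(size), size, size)              # row index
  gx <- matrix(seq_len(size), size, size, byrow = TRUE)
  coord <- if (s == 1L) gx else gy
  img <- base + stripe_amp * sin(2 * pi * stripe_freq * coord / size)
  u <- (gx - ctr) / size
  v <- (gy - ctr) / size
  if (y == 1L) {
    a <- (u + v) / sqrt(2)   # major axis at 45 degrees
    b <- (u - v) / sqrt(2)
    inside <- (a / 0.27)^2 + (b / 0.13)^2 <= 1
  } else {
    inside <- (u / 0.19)^2 + (v / 0.19)^2 <= 1
  }
  img[inside] <- img[inside] + lesion_gain
  img
}

#' Generate a synthetic labelled image dataset
#'
#' Produces grayscale images whose utility class is a morphological factor
#' (lesion shape) and whose sensitive attribute is an independent texture
#' factor (stripe orientation); `(y, s)` pairs are drawn from the 2x2 joint
#' distribution implied by the configured marginal rates and phi
#' correlation. Gaussian pixel noise is added and pixels are clipped to
#' `[0,1]`. Fully deterministic given the config seed.
#'
#' @param config an [image_gen_config()].
#' @return an `lsp_dataset` with `x` (n x size^2 matrix, images flattened
#'   column-major), `y` and `s`.
#' @export
generate_images <- function(config) {
  stopifnot(inherits(config, "image_gen_config"))
  with_seed(config$seed, {
    ys <- .sample_ys(config$n_samples, config$class_rate,
                     config$sensitive_rate, config$label_attr_correlation)
    sz <- config$image_size
    x <- matrix(0, config$n_samples, sz * sz)
    for (i in seq_len(config$n_samples)) {
      img <- .draw_image(sz, ys$y[i], ys$s[i])
      x[i, ] <- as.vector(img)
    }
    if (config$noise_sd > 0)
      x <- x + matrix(stats::rnorm(length(x), sd = config$noise_sd),
                      nrow(x), ncol(x))
    x[x < 0] <- 0
    x[x > 1] <- 1
    new_dataset(x, ys$y, ys$s, "image", image_size = sz)
  })
}

## ---- tabular generator ------------------------------------------------------

#' Configuration for the synthetic transaction-table generator
#'
#' Defaults emulate a heavily imbalanced fraud-detection table: 0.172%
#' positive prevalence and 28 standardized features, with the sensitive
#' attribute driven by the first quarter of the features.
#'
#' @param n_samples number of rows.
#' @param n_features number of numeric feature columns.
#' @param fraud_rate marginal prevalence of the positive task label, in (0,1).
#' @param sensitive_rate marginal prevalence of sensitive attribute 1.
#' @param fraud_coefs per-feature effect sizes of the task-label logistic
#'   model (length `n_features`).
#' @param sensitive_coefs per-feature effect sizes of the sensitive-attribute
#'   logistic model (length `n_features`).
#' @param seed integer RNG seed.
#' @return a list of class `tabular_gen_config`.
#' @export
tabular_gen_config <- function(n_samples = 20000L, n_features = 28L,
                               fraud_rate = 0.00172, sensitive_rate = 0.3,
                               fraud_coefs = NULL, sensitive_coefs = NULL,
                               seed = 1L) {
  if (is.null(fraud_coefs))
    fraud_coefs <- rep(c(1.5, 0), c(min(8L, n_features),
                                    max(0L, n_features - 8L)))
  if (is.null(sensitive_coefs))
    sensitive_coefs <- rep(c(2, 0), c(max(1L, n_features %/% 4L),
                                      n_features - max(1L, n_features %/% 4L)))
  stopifnot(n_samples >= 1L, n_features >= 1L,
            fraud_rate > 0, fraud_rate < 1,
            sensitive_rate > 0, sensitive_rate < 1)
  if (length(fraud_coefs) != n_features)
    stop("fraud_coefs must have length n_features (", n_features, "), got ",
         length(fraud_coefs))
  if (length(sensitive_coefs) != n_features)
    stop("sensitive_coefs must have length n_features (", n_features,
         "), got ", length(sensitive_coefs))
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 fraud_rate = fraud_rate, sensitive_rate = sensitive_rate,
                 fraud_coefs = fraud_coefs, sensitive_coefs = sensitive_coefs,
                 seed = as.integer(seed)),
            class = "tabular_gen_config")
}

# Intercept b0 such that mean(plogis(b0 + eta)) = rate over the realised eta.
.calibrate_intercept <- function(eta, rate) {
  f <- function(b0) mean(stats::plogis(b0 + eta)) - rate
  stats::uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
}

#' Generate a synthetic transaction table
#'
#' Features are standardized two-component Gaussian mixtures; the task label
#' follows `Bernoulli(plogis(b0 + fraud_coefs . x))` with the intercept
#' calibrated so the marginal prevalence matches `fraud_rate`, and the
#' sensitive attribute likewise from `sensitive_coefs`. Deterministic given
#' the config seed.
#'
#' @param config a [tabular_gen_config()].
#' @return an `lsp_dataset` with modality `"tabular"`.
#' @export
generate_transactions <- function(config) {
  stopifnot(inherits(config, "tabular_gen_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    p <- config$n_features
    comp <- matrix(sample(c(-1, 1), n * p, replace = TRUE), n, p)
    x <- (comp + matrix(stats::rnorm(n * p), n, p)) / sqrt(2)
    eta_y <- drop(x %*% config$fraud_coefs)
    b0_y <- .calibrate_intercept(eta_y, config$fraud_rate)
    y <- stats::rbinom(n, 1L, stats::plogis(b0_y + eta_y))
    eta_s <- drop(x %*% config$sensitive_coefs)
    b0_s <- .calibrate_intercept(eta_s, config$sensitive_rate)
    s <- stats::rbinom(n, 1L, stats::plogis(b0_s + eta_s))
    colnames(x) <- paste0("f", seq_len(p))
    new_dataset(x, y, s, "tabular")
  })
}

## ---- train/test split -------------------------------------------------------

#' Split a dataset into disjoint train and test partitions
#'
#' Shuffles the sample indices with the given seed and assigns the first
#' `floor(n * train_fraction)` to the training partition; sample/label/
#' sensitive alignment is preserved in both parts. With the floor rule a
#' 2637-sample set at fraction 0.8 yields partitions of 2109 and 528.
#'
#' @param data an `lsp_dataset`.
#' @param train_fraction fraction of samples assigned to training, in (0,1).
#' @param seed shuffle seed.
#' @return list with elements `train` and `test`, both `lsp_dataset`s.
#' @export
train_test_split <- function(data, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(data, "lsp_dataset"),
            train_fraction > 0, train_fraction < 1)
  n <- nrow(data$x)
  if (n < 2L) stop("need at least 2 samples to split")
  n_train <- floor(n * train_fraction)
  if (n_train < 1L || n_train >= n)
    stop("train_fraction ", train_fraction, " leaves an empty partition for n = ", n)
  idx <- with_seed(seed, sample.int(n))
  list(train = dataset_subset(data, idx[seq_len(n_train)]),
       test = dataset_subset(data, idx[(n_train + 1L):n]))
}
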
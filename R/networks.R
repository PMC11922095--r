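# Encoder / decoder / privacy-discriminator architectures and the latent
# split and obfuscation operators.

#' Network architecture specification
#'
#' Describes the LSP architecture for one modality. Defaults follow the
#' reference design: latent dimension 128 for images and 64 for tabular data,
#' an image encoder of four stride-2 convolution blocks with 32, 64, 128 and
#' 256 filters followed by one fully connected projection (five weight layers
#' in total), a three-layer fully connected encoder for tabular data, and a
#' three-hidden-layer adversary (512, 256, 128 units) with dropout 0.3.
#'
#' @param modality `"image"` or `"tabular"`.
#' @param input_shape for images, `c(height, width, channels)` (height and
#'   width must be equal and divisible by 16); for tabular, the number of
#'   feature columns.
#' @param latent_dim total latent dimension `d`; default 128 (image) or
#'   64 (tabular).
#' @param d_s size of the sensitive subspace `Z_s` (the first `d_s` latent
#'   coordinates); default `latent_dim / 8`.
#' @param conv_filters filter counts of the image encoder's convolution
#'   blocks.
#' @param fc_widths hidden widths of the tabular encoder.
#' @param discriminator_widths hidden widths of the privacy discriminator.
#' @param dropout dropout rate in the discriminator.
#' @param sensitive_cardinality number of sensitive-attribute classes
#'   (2 = binary).
#' @return an object of class `lsp_spec`.
#' @export
lsp_spec <- function(modality = c("image", "tabular"), input_shape,
                     latent_dim = NULL, d_s = NULL,
                     conv_filters = c(32L, 64L, 128L, 256L),
                     fc_widths = c(256L, 128L),
                     discriminator_widths = c(512L, 256L, 128L),
                     dropout = 0.3, sensitive_cardinality = 2L) {
  modality <- match.arg(modality)
  if (modality == "image") {
    if (length(input_shape) == 1L) input_shape <- c(input_shape, input_shape, 1L)
    if (length(input_shape) == 2L) input_shape <- c(input_shape, 1L)
    if (input_shape[1] != input_shape[2])
      stop("image inputs must be square")
    if (input_shape[1] %% 2^length(conv_filters) != 0L)
      stop("image size ", input_shape[1], " is not divisible by ",
           2^length(conv_filters),
           "; pad or resize the images before encoding")
    if (is.null(latent_dim)) latent_dim <- 128L
  } else {
    if (length(input_shape) != 1L || input_shape < 1L)
      stop("tabular input_shape must be a single positive feature count")
    if (is.null(latent_dim)) latent_dim <- 64L
  }
  if (is.null(d_s)) d_s <- max(1L, as.integer(latent_dim / 8))
  if (latent_dim < 2L) stop("latent_dim must be at least 2")
  # d_s = 0 is allowed as an explicit degenerate case (plain autoencoder)
  if (d_s < 0L || d_s >= latent_dim)
    stop("d_s must satisfy 0 <= d_s < latent_dim")
  if (any(c(conv_filters, fc_widths, discriminator_widths) < 1L))
    stop("layer widths must be positive")
  if (sensitive_cardinality < 2L)
    stop("sensitive_cardinality must be at least 2")
  structure(list(modality = modality,
                 input_shape = as.integer(input_shape),
                 latent_dim = as.integer(latent_dim),
                 d_s = as.integer(d_s),
                 d_ns = as.integer(latent_dim - d_s),
                 conv_filters = as.integer(conv_filters),
                 fc_widths = as.integer(fc_widths),
                 discriminator_widths = as.integer(discriminator_widths),
                 dropout = dropout,
                 sensitive_cardinality = as.integer(sensitive_cardinality)),
            class = "lsp_spec")
}

#' @export
print.lsp_spec <- function(x, ...) {
  cat("LSP network spec (", x$modality, ")\n", sep = "")
  cat("  input shape : ", paste(x$input_shape, collapse = "x"), "\n", sep = "")
  cat("  latent dim  : ", x$latent_dim, " (d_s = ", x$d_s,
      ", d_ns = ", x$d_ns, ")\n", sep = "")
  invisible(x)
}

#' Build the LSP encoder network
#'
#' Image modality: four stride-2 convolution blocks (batch norm + leaky ReLU,
#' slope 0.2) with expanding filter counts, then one fully connected layer to
#' the latent vector; pixel inputs in `[0,1]` are internally mapped to
#' `[-1,1]`. Tabular modality: three fully connected layers (batch norm +
#' leaky ReLU on the hidden ones) ending at the latent dimension.
#'
#' @param spec an [lsp_spec()].
#' @param seed integer seed for the parameter initialisation.
#' @return an internal network object.
#' @export
build_encoder <- function(spec, seed = 1L) {
  with_seed(seed, {
    layers <- list()
    if (spec$modality == "image") {
      sz <- spec$input_shape[1]
      C <- spec$input_shape[3]
      layers <- c(layers, list(layer_rescale(2, -1)))
      for (f in spec$conv_filters) {
        g <- conv_geometry(sz, sz, C, k = 3L, stride = 2L, pad = 1L)
        sz <- sz %/% 2L
        layers <- c(layers, list(layer_conv(g, f),
                                 layer_bn(f, act = "lrelu")))
        C <- f
      }
      layers <- c(layers, list(layer_dense(sz * sz * C, spec$latent_dim)))
    } else {
      widths <- c(spec$input_shape[1], spec$fc_widths, spec$latent_dim)
      for (i in seq_len(length(widths) - 1L)) {
        layers <- c(layers, list(layer_dense(widths[i], widths[i + 1L])))
        if (i < length(widths) - 1L)
          layers <- c(layers, list(layer_bn(widths[i + 1L], act = "lrelu")))
      }
    }
    net <- do.call(nn_network, layers)
    net$role <- "encoder"
    net$spec <- spec
    net
  })
}

#' Build the LSP decoder network
#'
#' Image modality: a fully connected layer expands the latent vector to a
#' small spatial seed tensor, followed by transposed-convolution blocks with
#' decreasing filter counts (batch norm + ReLU) that mirror the encoder, and
#' a final stride-1 convolution with tanh activation; outputs are rescaled
#' from `[-1,1]` to `[0,1]` at the interface. Tabular modality: three fully
#' connected layers with a linear output.
#'
#' @inheritParams build_encoder
#' @return an internal network object.
#' @export
build_decoder <- function(spec, seed = 1L) {
  with_seed(seed, {
    layers <- list()
    if (spec$modality == "image") {
      n_conv <- length(spec$conv_filters)
      seed_sz <- spec$input_shape[1] %/% 2L^n_conv
      C <- spec$conv_filters[n_conv]
      layers <- c(layers, list(layer_dense(spec$latent_dim, seed_sz^2 * C),
                               layer_bn(C, act = "relu")))
      up_filters <- c(rev(spec$conv_filters)[-1],
                      max(1L, spec$conv_filters[1] %/% 2L))
      sz <- seed_sz
      for (f in up_filters) {
        # adjoint of a stride-2 conv from (2sz x 2sz x f) down to (sz x sz x C)
        g <- conv_geometry(2L * sz, 2L * sz, f, k = 3L, stride = 2L, pad = 1L)
        stopifnot(g$P == sz * sz)
        layers <- c(layers, list(layer_tconv(g, C),
                                 layer_bn(f, act = "relu")))
        C <- f
        sz <- 2L * sz
      }
      # 1x1 output convolution: the last transposed-conv block already does
      # the spatial smoothing, so the head only mixes channels
      g_out <- conv_geometry(sz, sz, C, k = 1L, stride = 1L, pad = 0L)
      layers <- c(layers, list(layer_conv(g_out, spec$input_shape[3]),
                               layer_act("tanh"),
                               layer_rescale(0.5, 0.5)))
    } else {
      widths <- c(spec$latent_dim, rev(spec$fc_widths), spec$input_shape[1])
      for (i in seq_len(length(widths) - 1L)) {
        layers <- c(layers, list(layer_dense(widths[i], widths[i + 1L])))
        if (i < length(widths) - 1L)
          layers <- c(layers, list(layer_bn(widths[i + 1L], act = "relu")))
      }
    }
    net <- do.call(nn_network, layers)
    net$role <- "decoder"
    net$spec <- spec
    net
  })
}

#' Build a privacy discriminator
#'
#' A fully connected adversary with three hidden layers (default widths 512,
#' 256, 128), each followed by batch normalisation, ReLU and dropout
#' (rate 0.3), ending in a sigmoid head for binary sensitive attributes or a
#' softmax head for categorical ones. By default it attacks the released
#' nonsensitive code `z_ns`.
#'
#' @inheritParams build_encoder
#' @param input_dim length of the latent input; defaults to `spec$d_ns`
#'   (set `spec$latent_dim` to attack the full code).
#' @return an internal network object of class `lsp_network`.
#' @export
build_discriminator <- function(spec, seed = 1L, input_dim = spec$d_ns) {
  if (spec$sensitive_cardinality < 2L)
    stop("sensitive_cardinality must be at least 2")
  n_out <- if (spec$sensitive_cardinality == 2L) 1L else spec$sensitive_cardinality
  with_seed(seed, {
    layers <- list()
    widths <- c(input_dim, spec$discriminator_widths)
    for (i in seq_len(length(widths) - 1L)) {
      layers <- c(layers, list(layer_dense(widths[i], widths[i + 1L]),
                               layer_bn(widths[i + 1L], act = "relu"),
                               layer_dropout(spec$dropout)))
    }
    layers <- c(layers, list(layer_dense(widths[length(widths)], n_out),
                             layer_act(if (n_out == 1L) "sigmoid" else "softmax")))
    net <- do.call(nn_network, layers)
    net$role <- "discriminator"
    net$spec <- spec
    net$input_dim <- input_dim
    net$n_out <- n_out
    net
  })
}

#' Count the trainable parameters of a built network
#'
#' @param net a network built by [build_encoder()], [build_decoder()] or
#'   [build_discriminator()].
#' @return integer number of trainable scalars (weights, biases, batch-norm
#'   scale and shift).
#' @export
count_params <- function(net) nn_n_params(net)

## ---- user-facing tensors ----------------------------------------------------

# Users hand in samples as rows; the engine wants features x batch.
.as_feature_matrix <- function(x, spec) {
  if (inherits(x, "lsp_dataset")) x <- x$x
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  n_feat <- if (spec$modality == "image") prod(spec$input_shape)
            else spec$input_shape[1]
  if (ncol(x) != n_feat)
    stop("input has ", ncol(x), " features but the model expects ", n_feat)
  t(x)
}

#' Encode data into the latent space
#'
#' Maps inputs through the encoder in evaluation mode (deterministic) and
#' records the sensitive/nonsensitive split sizes.
#'
#' @param model a fitted [lsp()] object, or a list with elements `encoder`
#'   and `spec`.
#' @param x a matrix with one sample per row (images flattened column-major,
#'   pixels in `[0,1]`), or an `lsp_dataset`.
#' @return an object of class `lsp_latent`: a list with `z` (n x d matrix),
#'   `d_s` and `d_ns`.
#' @export
encode <- function(model, x) {
  X <- .as_feature_matrix(x, model$spec)
  z <- t(nn_forward(model$encoder, X, training = FALSE)$out)
  structure(list(z = z, d_s = model$spec$d_s, d_ns = model$spec$d_ns),
            class = "lsp_latent")
}

#' Decode latent codes back to data space
#'
#' @param model a fitted [lsp()] object or a list with `decoder` and `spec`.
#' @param z an `lsp_latent`, or a matrix of codes with one sample per row.
#' @return matrix with one reconstructed sample per row; image pixels lie in
#'   `[0,1]`.
#' @export
decode <- function(model, z) {
  if (inherits(z, "lsp_latent")) z <- z$z
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != model$spec$latent_dim)
    stop("latent codes have length ", ncol(z), " but the model expects ",
         model$spec$latent_dim)
  t(nn_forward(model$decoder, t(z), training = FALSE)$out)
}

#' Split a latent code into sensitive and nonsensitive parts
#'
#' The sensitive subspace `Z_s` occupies the first `d_s` coordinates by fixed
#' convention; concatenating the two parts restores the code exactly.
#'
#' @param z an `lsp_latent` object.
#' @return list with matrices `z_s` (n x d_s) and `z_ns` (n x d_ns).
#' @export
split_latent <- function(z) {
  stopifnot(inherits(z, "lsp_latent"))
  list(z_s = z$z[, seq_len(z$d_s), drop = FALSE],
       z_ns = z$z[, z$d_s + seq_len(z$d_ns), drop = FALSE])
}

#' Obfuscate data by neutralising the sensitive subspace
#'
#' Encodes the input, replaces the sensitive coordinates `z_s` with zeros,
#' with the training-set mean of `z_s`, or with draws from the training-set
#' empirical bank of `z_s` vectors, and decodes the edited code.
#'
#' @param model a fitted [lsp()] object; modes `"mean"` and `"resample"`
#'   additionally require fitted latent statistics
#'   (see [fit_latent_statistics()], done automatically by [lsp()]).
#' @param x matrix of samples (rows) or an `lsp_dataset`.
#' @param mode how to replace `z_s`: `"zero"`, `"mean"` or `"resample"`.
#' @param seed seed used by `"resample"` mode.
#' @return matrix of obfuscated samples, same shape as the input.
#' @export
obfuscate <- function(model, x, mode = c("zero", "mean", "resample"),
                      seed = 1L) {
  mode <- match.arg(mode)
  z <- encode(model, x)
  n <- nrow(z$z)
  d_s <- z$d_s
  if (d_s > 0L) {
    repl <- switch(mode,
      zero = matrix(0, n, d_s),
      mean = {
        if (is.null(model$latent_stats))
          stop("mode = 'mean' requires fitted latent statistics")
        matrix(model$latent_stats$mean_z_s, n, d_s, byrow = TRUE)
      },
      resample = {
        if (is.null(model$latent_stats))
          stop("mode = 'resample' requires fitted latent statistics")
        bank <- model$latent_stats$bank
        idx <- with_seed(seed, sample.int(nrow(bank), n, replace = TRUE))
        bank[idx, , drop = FALSE]
      })
    z$z[, seq_len(d_s)] <- repl
  }
  decode(model, z)
}
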
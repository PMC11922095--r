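# Adversarial training: alternating optimisation of the privacy
# discriminator against the encoder/decoder (plus a sensitive-routing head
# on Z_s), balancing reconstruction fidelity against sensitive-attribute
# leakage through the released code Z_ns.

#' Mean squared reconstruction error
#'
#' @param x,x_rec numeric arrays of identical shape.
#' @return mean of squared elementwise differences; 0 iff identical.
#' @export
reconstruction_loss <- function(x, x_rec) {
  if (!identical(dim(x), dim(x_rec)) || length(x) != length(x_rec))
    stop("x and x_rec must have identical shapes")
  mean((x - x_rec)^2)
}

#' Cross-entropy of sensitive-attribute predictions
#'
#' @param pred_probs predicted probabilities: for a binary attribute a vector
#'   (or 1-column matrix) of P(s = 1); for a categorical attribute an
#'   n x C matrix of class probabilities.
#' @param s observed sensitive attribute: 0/1 for binary, 1..C for
#'   categorical.
#' @return mean negative log-likelihood, `>= 0`.
#' @export
privacy_loss <- function(pred_probs, s) {
  p <- as.matrix(pred_probs)
  if (any(p < 0) || any(p > 1)) stop("pred_probs must lie in [0, 1]")
  eps <- 1e-12
  if (ncol(p) == 1L) {
    pv <- pmin(pmax(p[, 1L], eps), 1 - eps)
    mean(-(s * log(pv) + (1 - s) * log(1 - pv)))
  } else {
    idx <- cbind(seq_len(nrow(p)), as.integer(s))
    mean(-log(pmax(p[idx], eps)))
  }
}

# Confusion loss: mean cross-entropy of the predictions against the uniform
# distribution. Minimising it drives the discriminator's output towards
# chance without the vanishing-gradient saturation (disc confidently right)
# or the label-flipping overshoot (disc confidently wrong) of the raw
# min-max objective -gamma * CE(p, s).
ce_confusion_grad <- function(probs) {
  B <- ncol(probs)
  eps <- 1e-7
  pc <- pmin(pmax(probs, eps), 1 - eps)
  if (nrow(probs) == 1L) {
    loss <- mean(-0.5 * log(pc[1L, ]) - 0.5 * log(1 - pc[1L, ]))
    dp <- matrix((-0.5 / pc[1L, ] + 0.5 / (1 - pc[1L, ])) / B, 1L, B)
  } else {
    C <- nrow(probs)
    loss <- mean(-colSums(log(pc)) / C)
    dp <- -1 / (C * pc) / B
  }
  list(loss = loss, dprobs = dp)
}

# Between-group moment alignment of the nonsensitive code. The code is
# standardised per batch and coordinate (mean 0, sd 1; the scaling is
# treated as a constant in the gradient), then
#   L = sum_k (n_k/B) * ( ||mean_k(zh)||^2 + ||mean_k(zh^2) - mean(zh^2)||^2 )
# penalises group differences in first and second moments. Standardising
# makes the pressure scale-invariant: a group gap of a few pooled standard
# deviations is penalised equally hard wherever the code lives, which keeps
# the purge from stalling with a small absolute — but perfectly
# attackable — residual gap. The discriminator alone cannot dismantle the
# massively redundant encoding of a salient sensitive factor; this term
# contracts all of it at once.
group_align_grad <- function(zn, sb) {
  B <- ncol(zn)
  m <- rowMeans(zn)
  sdv <- sqrt(rowMeans(zn * zn) - m * m + 1e-8)
  zh <- (zn - m) / sdv
  zq <- zh * zh
  q <- rowMeans(zq)
  classes <- unique(sb)
  dzh <- matrix(0, nrow(zn), B)
  loss <- 0
  for (k in classes) {
    ik <- sb == k
    mk <- rowMeans(zh[, ik, drop = FALSE])            # overall mean is 0
    qk <- rowMeans(zq[, ik, drop = FALSE]) - q
    loss <- loss + sum(ik) / B * (sum(mk * mk) + sum(qk * qk))
    dzh[, ik] <- (2 / B) * mk + (4 / B) * qk * zh[, ik, drop = FALSE]
  }
  list(loss = loss, dz = dzh / sdv)
}

# Loss and gradient of mean cross-entropy w.r.t. predicted probabilities.
# probs: (1 x B) for binary (sigmoid head), (C x B) for categorical.
ce_loss_grad <- function(probs, s) {
  B <- ncol(probs)
  eps <- 1e-7
  pc <- pmin(pmax(probs, eps), 1 - eps)
  if (nrow(probs) == 1L) {
    sv <- as.numeric(s)
    loss <- mean(-(sv * log(pc[1L, ]) + (1 - sv) * log(1 - pc[1L, ])))
    dp <- matrix((pc[1L, ] - sv) / (pc[1L, ] * (1 - pc[1L, ])) / B, 1L, B)
  } else {
    idx <- cbind(as.integer(s), seq_len(B))
    loss <- mean(-log(pc[idx]))
    dp <- matrix(0, nrow(probs), B)
    dp[idx] <- -1 / pc[idx] / B
  }
  list(loss = loss, dprobs = dp)
}

#' Training configuration for adversarial LSP training
#'
#' @param gamma privacy weight: strength of the encoder's adversarial
#'   objective against the privacy discriminator (`>= 0`; 0 disables it).
#' @param lambda_s weight of the sensitive-routing head that pulls sensitive
#'   information into `Z_s` (`>= 0`).
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate (shared by all networks).
#' @param disc_steps_per_enc_step discriminator updates per encoder update.
#' @param beta1,beta2 Adam moment decay rates.
#' @param seed seed controlling data order, dropout and any other training
#'   randomness.
#' @return list of class `lsp_train_config`.
#' @export
lsp_train_config <- function(gamma = 0.2, lambda_s = 1, epochs = 50L,
                             batch_size = 64L, learning_rate = 1e-3,
                             disc_steps_per_enc_step = 1L,
                             beta1 = 0.9, beta2 = 0.999, seed = 1L) {
  if (gamma < 0) stop("gamma must be >= 0")
  if (lambda_s < 0) stop("lambda_s must be >= 0")
  stopifnot(epochs >= 1L, batch_size >= 1L, learning_rate > 0,
            disc_steps_per_enc_step >= 1L)
  structure(list(gamma = gamma, lambda_s = lambda_s,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 disc_steps_per_enc_step = as.integer(disc_steps_per_enc_step),
                 beta1 = beta1, beta2 = beta2, seed = as.integer(seed)),
            class = "lsp_train_config")
}

# Auxiliary sensitive-routing head: a linear classifier on z_s.
build_aux_head <- function(spec, seed = 1L) {
  n_out <- if (spec$sensitive_cardinality == 2L) 1L else spec$sensitive_cardinality
  with_seed(seed, {
    net <- nn_network(layer_dense(spec$d_s, n_out),
                      layer_act(if (n_out == 1L) "sigmoid" else "softmax"))
    net$role <- "aux_head"
    net
  })
}

#' Train an LSP model adversarially
#'
#' Alternates, per minibatch, (a) `disc_steps_per_enc_step` discriminator
#' updates minimising the cross-entropy of its sensitive-attribute
#' prediction from `z_ns` with the encoder frozen, and (b) one
#' encoder/decoder update minimising
#' `MSE(x, x_rec) + lambda_s * CE(aux(z_s), s) + gamma * CE(P(z_ns), uniform)`
#' with the discriminator frozen — the non-saturating "confusion" form of
#' the adversarial objective, which pushes the discriminator's output
#' towards chance instead of maximising its error (the raw min-max gradient
#' vanishes once the discriminator is confidently right). Fully seeded:
#' identical inputs and config give bit-identical histories.
#'
#' @param model list with `encoder`, `decoder`, `aux` (optional) and `spec`,
#'   as assembled by [lsp()]; networks from [build_encoder()] /
#'   [build_decoder()].
#' @param discriminator a network from [build_discriminator()].
#' @param data an `lsp_dataset` matching the model's modality.
#' @param config an [lsp_train_config()].
#' @return list with updated `model`, `discriminator` and `history` (class
#'   `lsp_history`: one row per epoch with mean reconstruction,
#'   discriminator, encoder-adversarial and routing losses).
#' @export
train_lsp <- function(model, discriminator, data, config) {
  stopifnot(inherits(data, "lsp_dataset"), inherits(config, "lsp_train_config"))
  if (data$modality != model$spec$modality)
    stop("data modality does not match the model spec")
  spec <- model$spec
  d <- spec$latent_dim
  d_s <- spec$d_s
  rows_s <- seq_len(d_s)
  rows_ns <- (d_s + 1L):d
  Xall <- t(data$x)
  sall <- if (spec$sensitive_cardinality == 2L) data$s else data$s + 1L
  n <- ncol(Xall)
  use_aux <- config$lambda_s > 0 && d_s > 0L && !is.null(model$aux)

  enc <- net_clone_params(model$encoder)
  dec <- net_clone_params(model$decoder)
  aux <- if (!is.null(model$aux)) net_clone_params(model$aux)
  disc <- net_clone_params(discriminator)
  st_enc <- adam_state(enc); st_dec <- adam_state(dec)
  st_disc <- adam_state(disc)
  st_aux <- if (use_aux) adam_state(aux)
  t_enc <- 0L; t_disc <- 0L
  hist <- vector("list", config$epochs)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      acc <- c(recon = 0, disc = 0, adv = 0, routing = 0)
      n_b <- 0L
      for (b0 in starts) {
        idx <- perm[b0:min(b0 + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next   # batch norm needs >= 2 samples
        Xb <- Xall[, idx, drop = FALSE]
        sb <- sall[idx]

        ## one encoder forward serves the frozen-encoder discriminator steps
        ## and the encoder/decoder step (the encoder is not updated between)
        fe <- nn_forward(enc, Xb, training = TRUE, update_stats = TRUE)
        enc <- fe$net
        z <- fe$out

        ## (a) discriminator steps: encoder frozen
        dloss <- NA_real_
        for (k in seq_len(config$disc_steps_per_enc_step)) {
          fp <- nn_forward(disc, z[rows_ns, , drop = FALSE],
                           training = TRUE, update_stats = TRUE)
          disc <- fp$net
          cg <- ce_loss_grad(fp$out, sb)
          dloss <- cg$loss
          bw <- nn_backward(disc, fp$caches, cg$dprobs)
          t_disc <- t_disc + 1L
          adam_step(disc, st_disc, bw$grads, config$learning_rate,
                    t_disc, config$beta1, config$beta2)
        }

        ## (b) encoder/decoder step: discriminator frozen
        fd <- nn_forward(dec, z, training = TRUE, update_stats = TRUE)
        dec <- fd$net
        rec <- fd$out
        rloss <- mean((rec - Xb)^2)
        bdec <- nn_backward(dec, fd$caches, 2 * (rec - Xb) / length(rec))
        dz <- bdec$dX
        rout <- 0
        if (use_aux) {
          fa <- nn_forward(aux, z[rows_s, , drop = FALSE], training = TRUE,
                           update_stats = TRUE)
          aux <- fa$net
          ca <- ce_loss_grad(fa$out, sb)
          rout <- ca$loss
          ba <- nn_backward(aux, fa$caches, ca$dprobs)
          dz[rows_s, ] <- dz[rows_s, ] + config$lambda_s * ba$dX
        }
        # the frozen discriminator is applied in evaluation mode: with batch
        # statistics the encoder could lower the confusion loss by shifting
        # whole-batch moments (changing the adversary's normalisation)
        # without removing per-sample information
        fp <- nn_forward(disc, z[rows_ns, , drop = FALSE], training = FALSE)
        cp <- ce_confusion_grad(fp$out)
        ga <- group_align_grad(z[rows_ns, , drop = FALSE], sb)
        aloss <- cp$loss + ga$loss
        if (config$gamma > 0) {
          bp <- nn_backward(disc, fp$caches, cp$dprobs)
          dz[rows_ns, ] <- dz[rows_ns, ] +
            config$gamma * (bp$dX + ga$dz)
        }
        benc <- nn_backward(enc, fe$caches, dz)
        t_enc <- t_enc + 1L
        adam_step(enc, st_enc, benc$grads, config$learning_rate,
                  t_enc, config$beta1, config$beta2)
        adam_step(dec, st_dec, bdec$grads, config$learning_rate,
                  t_enc, config$beta1, config$beta2)
        if (use_aux)
          adam_step(aux, st_aux, ba$grads, config$learning_rate,
                    t_enc, config$beta1, config$beta2)

        if (!all(is.finite(c(rloss, dloss, aloss, rout))))
          stop("non-finite loss at epoch ", epoch, ", batch offset ", b0,
               " (recon=", rloss, ", disc=", dloss, ", adv=", aloss, ")")
        acc <- acc + c(rloss, dloss, aloss, rout)
        n_b <- n_b + 1L
      }
      acc <- acc / n_b
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  recon_loss = acc[["recon"]],
                                  disc_loss = acc[["disc"]],
                                  adv_loss = acc[["adv"]],
                                  routing_loss = acc[["routing"]])
    }
  })
  history <- do.call(rbind, hist)
  class(history) <- c("lsp_history", "data.frame")
  attr(history, "final_recon") <- history$recon_loss[nrow(history)]
  model$encoder <- enc
  model$decoder <- dec
  model$aux <- aux
  list(model = model, discriminator = disc, history = history)
}

#' Fit latent statistics of the sensitive subspace
#'
#' Encodes the data in evaluation mode and stores the per-coordinate mean of
#' `z_s` together with a seeded bank of `z_s` vectors (at most `cap` rows),
#' supporting the `"mean"` and `"resample"` obfuscation modes.
#'
#' @param model a fitted [lsp()] object or a list with `encoder` and `spec`.
#' @param data a non-empty `lsp_dataset`.
#' @param cap maximum number of stored `z_s` vectors.
#' @param seed seed for the subsample when `n > cap`.
#' @return list with `mean_z_s` and matrix `bank`.
#' @export
fit_latent_statistics <- function(model, data, cap = 1024L, seed = 1L) {
  stopifnot(inherits(data, "lsp_dataset"))
  if (nrow(data$x) == 0L) stop("cannot fit latent statistics on empty data")
  zs <- split_latent(encode(model, data))$z_s
  bank <- if (nrow(zs) > cap) {
    zs[with_seed(seed, sample.int(nrow(zs), cap)), , drop = FALSE]
  } else zs
  list(mean_z_s = colMeans(zs), bank = bank)
}

## ---- model-fitting front end ------------------------------------------------

#' Fit a latent space projection model
#'
#' Builds the encoder, decoder, sensitive-routing head and privacy
#' discriminator for the data's modality, trains them adversarially with
#' [train_lsp()], and fits the latent statistics needed for obfuscation.
#' The returned object supports `print()`, `summary()`, `plot()` (training
#' history) and `predict()` (obfuscation, reconstruction, latent codes).
#'
#' @param data an `lsp_dataset` (see [generate_images()],
#'   [generate_transactions()] or [read_dataset()]).
#' @param gamma privacy weight of the adversarial objective.
#' @param d_s sensitive-subspace size; default `latent_dim / 8`.
#' @param latent_dim total latent dimension; default 128 (image), 64
#'   (tabular).
#' @param epochs,batch_size,learning_rate,lambda_s,disc_steps_per_enc_step
#'   training hyperparameters, see [lsp_train_config()].
#' @param spec optionally a full [lsp_spec()] overriding the derived one.
#' @param seed master seed for initialisation and training.
#' @return an object of class `lsp`.
#' @examples
#' d <- generate_images(image_gen_config(n_samples = 64, seed = 1))
#' fit <- lsp(d, gamma = 0.2, epochs = 1, seed = 1)
#' print(fit)
#' obf <- predict(fit, d, type = "obfuscated")
#' @export
lsp <- function(data, gamma = 0.2, d_s = NULL, latent_dim = NULL,
                epochs = 50L, batch_size = 64L, learning_rate = 1e-3,
                lambda_s = 1, disc_steps_per_enc_step = 1L,
                spec = NULL, seed = 1L) {
  stopifnot(inherits(data, "lsp_dataset"))
  if (is.null(spec)) {
    spec <- if (data$modality == "image") {
      lsp_spec("image", c(data$image_size, data$image_size, data$channels),
               latent_dim = latent_dim, d_s = d_s)
    } else {
      lsp_spec("tabular", ncol(data$x), latent_dim = latent_dim, d_s = d_s)
    }
  }
  config <- lsp_train_config(gamma = gamma, lambda_s = lambda_s,
                             epochs = epochs, batch_size = batch_size,
                             learning_rate = learning_rate,
                             disc_steps_per_enc_step = disc_steps_per_enc_step,
                             seed = seed)
  model <- list(encoder = build_encoder(spec, seed),
                decoder = build_decoder(spec, seed + 1L),
                aux = if (spec$d_s > 0L) build_aux_head(spec, seed + 3L),
                spec = spec)
  disc <- build_discriminator(spec, seed + 2L)
  tr <- train_lsp(model, disc, data, config)
  obj <- tr$model
  obj$discriminator <- tr$discriminator
  obj$config <- config
  obj$history <- tr$history
  obj$latent_stats <- fit_latent_statistics(tr$model, data, seed = seed)
  obj$n_train <- nrow(data$x)
  class(obj) <- "lsp"
  obj
}

#' @export
print.lsp <- function(x, ...) {
  cat("Latent space projection model (", x$spec$modality, ")\n", sep = "")
  cat("  latent dim ", x$spec$latent_dim, " = d_s ", x$spec$d_s,
      " + d_ns ", x$spec$d_ns, "\n", sep = "")
  cat("  privacy weight gamma = ", x$config$gamma,
      ", trained ", x$config$epochs, " epochs on ", x$n_train,
      " samples\n", sep = "")
  cat("  final reconstruction MSE: ",
      signif(attr(x$history, "final_recon"), 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.lsp <- function(object, ...) {
  h <- object$history
  structure(list(spec = object$spec, config = object$config,
                 n_train = object$n_train,
                 first_epoch = h[1L, ], last_epoch = h[nrow(h), ],
                 n_params = c(encoder = count_params(object$encoder),
                              decoder = count_params(object$decoder),
                              discriminator = count_params(object$discriminator))),
            class = "summary.lsp")
}

#' @export
print.summary.lsp <- function(x, ...) {
  cat("LSP model summary\n")
  print(x$spec)
  cat("  gamma = ", x$config$gamma, ", lambda_s = ", x$config$lambda_s,
      ", epochs = ", x$config$epochs, ", batch = ", x$config$batch_size,
      "\n", sep = "")
  cat("  parameters: encoder ", x$n_params["encoder"], ", decoder ",
      x$n_params["decoder"], ", discriminator ",
      x$n_params["discriminator"], "\n", sep = "")
  cat("  reconstruction MSE epoch 1: ", signif(x$first_epoch$recon_loss, 4),
      " -> epoch ", x$last_epoch$epoch, ": ",
      signif(x$last_epoch$recon_loss, 4), "\n", sep = "")
  invisible(x)
}

#' Predict method for LSP models
#'
#' @param object a fitted [lsp()] model.
#' @param newdata matrix of samples (rows) or an `lsp_dataset`.
#' @param type `"obfuscated"` (decode with `z_s` neutralised),
#'   `"reconstruction"` (plain autoencoder round trip), `"latent"` (full
#'   codes), `"z_ns"` or `"z_s"` (the released / sensitive code blocks).
#' @param mode `z_s` replacement mode for `type = "obfuscated"`, see
#'   [obfuscate()].
#' @param seed seed for `mode = "resample"`.
#' @param ... unused.
#' @return a matrix, one row per input sample.
#' @export
predict.lsp <- function(object, newdata,
                        type = c("obfuscated", "reconstruction", "latent",
                                 "z_ns", "z_s"),
                        mode = "zero", seed = 1L, ...) {
  type <- match.arg(type)
  switch(type,
    obfuscated = obfuscate(object, newdata, mode = mode, seed = seed),
    reconstruction = decode(object, encode(object, newdata)),
    latent = encode(object, newdata)$z,
    z_ns = split_latent(encode(object, newdata))$z_ns,
    z_s = split_latent(encode(object, newdata))$z_s)
}

#' Plot LSP training history
#'
#' Draws the per-epoch reconstruction loss together with the discriminator
#' and encoder-adversarial cross-entropies.
#'
#' @param x a fitted [lsp()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lsp <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$recon_loss, h$disc_loss, h$adv_loss),
                    type = "l", lty = 1, lwd = 2,
                    col = c("black", "firebrick", "steelblue"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright",
                   c("reconstruction", "discriminator CE", "encoder adv CE"),
                   col = c("black", "firebrick", "steelblue"), lty = 1, lwd = 2,
                   bty = "n")
  invisible(x)
}
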
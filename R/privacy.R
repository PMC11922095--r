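# Post-hoc privacy evaluation: attribute-inference attacks on released
# representations, the protection score, and a model-inversion attack.

#' Normalised privacy protection score
#'
#' Maps an attacker's held-out accuracy `a` and the majority-class chance
#' rate `c` to `100 * (1 - max(0, (a - c) / (1 - c)))`: 100 means the attack
#' is no better than always guessing the majority class, 0 means a perfect
#' attack. Clamped to `[0, 100]`.
#'
#' @param a attack accuracy in `[0, 1]`.
#' @param c chance rate (majority-class frequency of the sensitive attribute
#'   on the evaluation split), in `[0, 1)`.
#' @return protection percentage in `[0, 100]`.
#' @export
protection_score <- function(a, c) {
  if (any(a < 0 | a > 1)) stop("accuracy a must lie in [0, 1]")
  if (any(c < 0) || any(c >= 1))
    stop("chance rate c must lie in [0, 1); c = 1 leaves the advantage undefined")
  pmin(pmax(100 * (1 - pmax(0, (a - c) / (1 - c))), 0), 100)
}

#' Configuration of the attribute-inference attacker
#'
#' @param train_fraction fraction of the supplied samples used to train the
#'   attacker; the rest is the held-out evaluation split.
#' @param epochs,batch_size,learning_rate attacker training hyperparameters.
#' @param widths hidden widths of the attacker network (the discriminator
#'   family: 512/256/128 by default).
#' @param dropout attacker dropout rate.
#' @return list of class `attack_config`.
#' @export
attack_config <- function(train_fraction = 0.7, epochs = 30L,
                          batch_size = 64L, learning_rate = 1e-3,
                          widths = c(512L, 256L, 128L), dropout = 0.3) {
  stopifnot(train_fraction > 0, train_fraction < 1, epochs >= 1)
  structure(list(train_fraction = train_fraction, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 widths = as.integer(widths), dropout = dropout),
            class = "attack_config")
}

# Train a classifier network of the discriminator family on (X, s);
# X is (features x n), s in {0,1} or 1..C. Seeded and self-contained.
train_attacker_net <- function(net, X, s, epochs, batch_size, lr, seed) {
  net <- net_clone_params(net)
  st <- adam_state(net)
  n <- ncol(X)
  t_step <- 0L
  with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      perm <- sample.int(n)
      for (b0 in seq(1L, n, by = batch_size)) {
        idx <- perm[b0:min(b0 + batch_size - 1L, n)]
        if (length(idx) < 2L) next
        fp <- nn_forward(net, X[, idx, drop = FALSE], training = TRUE)
        net <- fp$net
        cg <- ce_loss_grad(fp$out, s[idx])
        bw <- nn_backward(net, fp$caches, cg$dprobs)
        t_step <- t_step + 1L
        adam_step(net, st, bw$grads, lr, t_step)
      }
    }
  })
  net
}

# predicted class labels (same coding as s) from a classifier net, eval mode
predict_attacker <- function(net, X) {
  p <- nn_forward(net, X, training = FALSE)$out
  if (nrow(p) == 1L) as.integer(p[1L, ] > 0.5) else max.col(t(p))
}

#' Attribute-inference attack on released representations
#'
#' Trains a fresh privacy-discriminator-family network to predict the
#' sensitive attribute from released representations (typically `z_ns`),
#' then reports its held-out accuracy, the majority-class chance rate and
#' the [protection_score()]. The attacker never sees the evaluation split.
#'
#' @param latents numeric matrix, one released representation per row.
#' @param s sensitive attribute per row (binary 0/1 or categorical 1..C).
#' @param config an [attack_config()].
#' @param seed seed for the split and attacker training.
#' @return list with `attacker` (the trained network) and `report` (class
#'   `privacy_report`): attack accuracy, chance rate, protection percentage,
#'   attack type, `n_eval`.
#' @export
attribute_inference_attack <- function(latents, s, config = attack_config(),
                                       seed = 1L) {
  latents <- as.matrix(latents)
  n <- nrow(latents)
  stopifnot(n == length(s))
  classes <- sort(unique(s))
  if (length(classes) < 2L)
    stop("sensitive attribute has a single class; chance rate would be 1 ",
         "and the attacker advantage is undefined")
  binary <- length(classes) == 2L && all(classes %in% c(0L, 1L))
  s_int <- if (binary) as.integer(s) else match(s, classes)
  idx <- with_seed(seed, sample.int(n))
  n_train <- floor(n * config$train_fraction)
  if (n_train < 1L || n_train >= n) stop("attack splits must both be non-empty")
  tr <- idx[seq_len(n_train)]
  te <- idx[(n_train + 1L):n]
  spec <- lsp_spec("tabular", ncol(latents),
                   latent_dim = max(2L, min(ncol(latents), 64L)),
                   discriminator_widths = config$widths,
                   dropout = config$dropout,
                   sensitive_cardinality = max(2L, length(classes)))
  net <- build_discriminator(spec, seed = seed + 1L, input_dim = ncol(latents))
  Xt <- t(latents)
  net <- train_attacker_net(net, Xt[, tr, drop = FALSE], s_int[tr],
                            config$epochs, config$batch_size,
                            config$learning_rate, seed + 2L)
  pred <- predict_attacker(net, Xt[, te, drop = FALSE])
  a <- mean(pred == s_int[te])
  c_rate <- max(table(s_int[te])) / length(te)
  report <- structure(
    list(attack_accuracy = a, chance_rate = as.numeric(c_rate),
         protection_pct = protection_score(a, c_rate),
         attack = "attribute_inference", n_eval = length(te)),
    class = "privacy_report")
  list(attacker = net, report = report)
}

#' @export
print.privacy_report <- function(x, ...) {
  cat("Attribute-inference attack (n_eval = ", x$n_eval, ")\n", sep = "")
  cat(sprintf("  attack accuracy : %.4f (chance %.4f)\n",
              x$attack_accuracy, x$chance_rate))
  cat(sprintf("  protection      : %.1f%%\n", x$protection_pct))
  invisible(x)
}

#' Model-inversion attack on released codes
#'
#' The attacker observes `(x, z_ns)` pairs for a public dataset, fits a
#' ridge-regression inverse mapping from codes back to images, applies it to
#' the private dataset's codes, and counts an inversion as successful when
#' the SSIM between the inverted and the true image exceeds `tau`.
#'
#' @param model a fitted [lsp()] image model, or a function mapping a sample
#'   matrix to released codes (useful for worst-case analyses such as an
#'   identity release).
#' @param public_data `lsp_dataset` (image) the attacker can pair with codes.
#' @param private_data `lsp_dataset` (image) being attacked.
#' @param tau SSIM success threshold (default 0.8).
#' @param seed seed (kept for interface symmetry; the ridge fit is
#'   deterministic).
#' @param lambda ridge penalty of the inverse regression.
#' @return an `inversion_report`: per-sample SSIM, `tau`, `success_rate`,
#'   `n`.
#' @export
model_inversion_attack <- function(model, public_data, private_data,
                                   tau = 0.8, seed = 1L, lambda = 1e-3) {
  stopifnot(inherits(public_data, "lsp_dataset"),
            inherits(private_data, "lsp_dataset"))
  if (public_data$modality != "image" || private_data$modality != "image")
    stop("model inversion is implemented for the image modality only")
  codes <- function(x) {
    if (is.function(model)) model(x) else
      split_latent(encode(model, x))$z_ns
  }
  Zp <- cbind(1, codes(public_data$x))
  Xp <- public_data$x
  G <- crossprod(Zp) + lambda * diag(ncol(Zp))
  Bhat <- solve(G, crossprod(Zp, Xp))
  Zq <- cbind(1, codes(private_data$x))
  Xhat <- Zq %*% Bhat
  Xhat[Xhat < 0] <- 0
  Xhat[Xhat > 1] <- 1
  sz <- private_data$image_size
  sims <- vapply(seq_len(nrow(Xhat)), function(i) {
    ssim(matrix(private_data$x[i, ], sz, sz), matrix(Xhat[i, ], sz, sz))
  }, 0)
  structure(list(similarity = sims, tau = tau,
                 success_rate = mean(sims > tau), n = length(sims)),
            class = "inversion_report")
}

#' @export
print.inversion_report <- function(x, ...) {
  cat("Model-inversion attack (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  success rate (SSIM > %.2f): %.1f%%\n",
              x$tau, 100 * x$success_rate))
  cat(sprintf("  median SSIM: %.3f\n", stats::median(x$similarity)))
  invisible(x)
}
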
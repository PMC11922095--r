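# Minimal seeded neural-network engine used by the LSP encoder, decoder and
# privacy discriminator. Networks are plain lists of layers; every tensor is
# stored as a (features x batch) matrix. Convolutions are expressed as sparse
# patch-extraction operators (im2col) so that the heavy lifting is one dense
# GEMM per layer; transposed convolutions apply the adjoint of the same
# operator. All randomness (init, dropout, shuffling) goes through R's global
# RNG so a single set.seed() pins an entire run.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library functions do not disturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

## ---- convolution geometry ---------------------------------------------------

# im2col geometry for a conv with square kernel `k`, stride `s`, zero padding
# `pad`, input (H x W x C). Feature vectors use a channel-fastest layout
# (index = (spatial - 1) * C + c, spatial column-major): with it the GEMM
# output (C_out x P*B) *is* the next layer's input after a zero-copy reshape,
# so no array permutes are ever needed. `gather` maps patch-matrix entry
# (p-1)*K + kk to its input index, with sentinel N+1 for a padding zero; the
# adjoint (col2im scatter-add) is served by `rowsum()` over the same map.
conv_geometry <- function(H, W, C, k, stride, pad) {
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  K <- k * k * C
  P <- Ho * Wo
  N <- H * W * C
  g <- expand.grid(c = seq_len(C), ki = seq_len(k), kj = seq_len(k),
                   or = seq_len(Ho), oc = seq_len(Wo))
  iy <- (g$or - 1L) * stride - pad + g$ki
  ix <- (g$oc - 1L) * stride - pad + g$kj
  p  <- (g$oc - 1L) * Ho + g$or
  inb <- iy >= 1L & iy <= H & ix >= 1L & ix <= W
  cols <- ifelse(inb, ((ix - 1L) * H + iy - 1L) * C + g$c, N + 1L)
  kk <- (g$kj - 1L) * k * C + (g$ki - 1L) * C + g$c
  gather <- integer(P * K)
  gather[(p - 1L) * K + kk] <- cols
  list(gather = gather, scatter_rows = sort(unique(cols)),
       H = H, W = W, C = C, Ho = Ho, Wo = Wo,
       K = K, P = P, N = N, k = k, stride = stride, pad = pad)
}

# patches (K x P*B) from input X (N x B); compiled gather.
.im2col <- function(geom, X, B) cpp_im2col(X, geom$gather, geom$K)

# adjoint: accumulate patch values (P*K x B) back onto the input grid,
# dropping padding-sentinel contributions; compiled scatter-add.
.col2im <- function(geom, dP, B) cpp_col2im(dP, geom$gather, geom$N)

## ---- weight init ------------------------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

## ---- layer constructors -----------------------------------------------------

layer_dense <- function(n_in, n_out) {
  list(type = "dense",
       params = list(W = he_init(n_out, n_in, n_in), b = matrix(0, n_out, 1)))
}

# conv: weights (Cout x K); input (H*W*C x B) channel-major, output
# (Ho*Wo*Cout x B) channel-major.
layer_conv <- function(geom, C_out) {
  list(type = "conv", geom = geom, C_out = C_out,
       params = list(W = he_init(C_out, geom$K, geom$K),
                     b = matrix(0, C_out, 1)))
}

# tconv: adjoint of a conv whose *input* is this layer's output. `geom` maps
# (Ho_big x Wo_big x C_out) -> P positions; forward here upsamples from
# (geom$Ho*geom$Wo*C_in) to (geom$H*geom$W*geom$C).
layer_tconv <- function(geom, C_in) {
  list(type = "tconv", geom = geom, C_in = C_in, C_out = geom$C,
       params = list(W = he_init(C_in, geom$K, geom$K),
                     b = matrix(0, geom$C, 1)))
}

# Batch normalisation over `groups` channels, optionally fused with the
# activation that always follows it in these architectures (one less pass
# over the tensor). With the channel-fastest layout channel c owns rows
# c, c + groups, c + 2*groups, ...; dense layers use groups = n_units.
layer_bn <- function(groups, act = c("none", "relu", "lrelu"), alpha = 0.2,
                     momentum = 0.1, eps = 1e-5) {
  act <- match.arg(act)
  list(type = "bn", groups = groups, act = act,
       act_alpha = switch(act, none = 1, relu = 0, lrelu = alpha),
       momentum = momentum, eps = eps,
       params = list(gamma = rep(1, groups), beta = rep(0, groups)),
       run_mean = rep(0, groups), run_var = rep(1, groups))
}

layer_act <- function(fun = c("lrelu", "relu", "tanh", "sigmoid", "softmax"),
                      alpha = 0.2) {
  list(type = "act", fun = match.arg(fun), alpha = alpha, params = list())
}

layer_dropout <- function(rate) {
  list(type = "dropout", rate = rate, params = list())
}

# Fixed affine map y = a*x + b (no parameters); used for the [0,1] <-> [-1,1]
# pixel contract at the model boundary.
layer_rescale <- function(a, b) {
  list(type = "rescale", a = a, b = b, params = list())
}

## ---- forward / backward -----------------------------------------------------

layer_forward <- function(layer, X, training = FALSE, update_stats = training) {
  B <- ncol(X)
  switch(layer$type,
    dense = {
      out <- layer$params$W %*% X + as.vector(layer$params$b)
      list(out = out, cache = list(X = X), layer = layer)
    },
    conv = {
      g <- layer$geom
      out <- cpp_conv_fwd(X, g$gather, layer$params$W,
                          as.vector(layer$params$b))
      list(out = out, cache = list(X = X, B = B), layer = layer)
    },
    tconv = {
      g <- layer$geom
      out <- cpp_tconv_fwd(X, g$gather, layer$params$W,
                           as.vector(layer$params$b), g$N)
      list(out = out, cache = list(X = X, B = B), layer = layer)
    },
    bn = {
      gr <- layer$groups; m <- length(X) / gr
      if (training) {
        st <- cpp_bn_stats(X, gr)
        mu <- st$mean; va <- st$var
        if (update_stats) {
          mom <- layer$momentum
          layer$run_mean <- (1 - mom) * layer$run_mean + mom * mu
          layer$run_var  <- (1 - mom) * layer$run_var  + mom * va * m / max(m - 1, 1)
        }
      } else {
        mu <- layer$run_mean; va <- layer$run_var
      }
      inv_sd <- 1 / sqrt(va + layer$eps)
      a <- layer$params$gamma * inv_sd
      out <- cpp_scale_shift_act(X, a, layer$params$beta - mu * a,
                                 layer$act_alpha)
      list(out = out,
           cache = list(X = X, out = out, mu = mu, inv_sd = inv_sd, m = m,
                        B = B, training = training),
           layer = layer)
    },
    act = {
      out <- switch(layer$fun,
        lrelu = cpp_lrelu(X, layer$alpha),
        relu = cpp_lrelu(X, 0),
        tanh = tanh(X),
        sigmoid = stats::plogis(X),
        softmax = {
          E <- exp(sweep(X, 2, apply(X, 2, max)))
          sweep(E, 2, colSums(E), "/")
        })
      list(out = out, cache = list(out = out), layer = layer)
    },
    dropout = {
      if (training && layer$rate > 0) {
        mask <- (stats::runif(length(X)) >= layer$rate) / (1 - layer$rate)
        dim(mask) <- dim(X)
        list(out = X * mask, cache = list(mask = mask), layer = layer)
      } else {
        list(out = X, cache = list(mask = NULL), layer = layer)
      }
    },
    rescale = list(out = layer$a * X + layer$b, cache = NULL, layer = layer),
    stop("unknown layer type: ", layer$type)
  )
}

layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
    dense = {
      list(dX = crossprod(layer$params$W, dY),
           grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
    },
    conv = {
      g <- layer$geom
      bw <- cpp_conv_bwd(dY, cache$X, g$gather, layer$params$W, TRUE)
      list(dX = bw$dX, grads = list(W = bw$dW, b = bw$db))
    },
    tconv = {
      g <- layer$geom
      bw <- cpp_tconv_bwd(dY, cache$X, g$gather, layer$params$W, g$C)
      list(dX = bw$dX, grads = list(W = bw$dW, b = bw$db))
    },
    bn = {
      bw <- cpp_bn_bwd(cache$X, dY, cache$out, cache$mu, cache$inv_sd,
                       layer$params$gamma, layer$act_alpha, cache$training)
      list(dX = bw$dX, grads = list(gamma = bw$dgamma, beta = bw$dbeta))
    },
    act = {
      dX <- switch(layer$fun,
        lrelu = cpp_lrelu_grad(dY, cache$out, layer$alpha),
        relu = cpp_lrelu_grad(dY, cache$out, 0),
        tanh = dY * (1 - cache$out^2),
        sigmoid = dY * cache$out * (1 - cache$out),
        softmax = {
          s <- colSums(dY * cache$out)
          cache$out * sweep(dY, 2, s)
        })
      list(dX = dX, grads = list())
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = list())
      else list(dX = dY * cache$mask, grads = list())
    },
    rescale = list(dX = layer$a * dY, grads = list()),
    stop("unknown layer type")
  )
}

## ---- network container ------------------------------------------------------

nn_network <- function(...) {
  structure(list(layers = list(...)), class = "lsp_network")
}

nn_forward <- function(net, X, training = FALSE, update_stats = training) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    fw <- layer_forward(net$layers[[i]], X, training, update_stats)
    net$layers[[i]] <- fw$layer   # bn running stats may have moved
    caches[[i]] <- fw$cache
    X <- fw$out
  }
  list(out = X, caches = caches, net = net)
}

nn_backward <- function(net, caches, dY) {
  n <- length(net$layers)
  grads <- vector("list", n)
  for (i in rev(seq_len(n))) {
    bw <- layer_backward(net$layers[[i]], caches[[i]], dY)
    grads[[i]] <- bw$grads
    dY <- bw$dX
  }
  list(dX = dY, grads = grads)
}

#' Count trainable parameters of a network
#' @param net an internal `lsp_network`.
#' @return integer parameter count.
#' @keywords internal
nn_n_params <- function(net) {
  sum(vapply(net$layers,
             function(l) sum(vapply(l$params, length, 0L)), 0L))
}

## ---- Adam -------------------------------------------------------------------

adam_state <- function(net) {
  lapply(net$layers, function(l) lapply(l$params, function(p) {
    list(m = p * 0, v = p * 0)
  }))
}

# In-place Adam: parameters and moment estimates are updated without
# reallocation. The training loop owns its networks exclusively (it clones
# all parameters on entry), so the mutation never leaks to caller objects.
adam_step <- function(net, state, grads, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    ps <- net$layers[[i]]$params
    if (!length(ps)) next
    for (nm in names(ps)) {
      st <- state[[i]][[nm]]
      cpp_adam(ps[[nm]], st$m, st$v, grads[[i]][[nm]],
               lr, beta1, beta2, bc1, bc2, eps)
    }
  }
  invisible(net)
}

# Deep-copy all trainable parameters so in-place optimisation cannot touch
# objects the caller still holds.
net_clone_params <- function(net) {
  for (i in seq_along(net$layers)) {
    ps <- net$layers[[i]]$params
    if (!length(ps)) next
    for (nm in names(ps)) net$layers[[i]]$params[[nm]] <- ps[[nm]] + 0
  }
  net
}

# Flat numeric fingerprint of all parameters; used to assert that frozen
# networks really are frozen during alternating optimisation.
nn_param_hash <- function(net) {
  sum(unlist(lapply(net$layers, function(l)
    vapply(l$params, function(p) sum(p) + sum(p * p), 0))))
}
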
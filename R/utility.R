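# Utility of released data: downstream task performance, image fidelity
# (PSNR / SSIM) and group-fairness gaps.

#' Peak signal-to-noise ratio
#'
#' `10 * log10(max_val^2 / MSE)`; identical inputs return the documented
#' `Inf` sentinel rather than raising an error.
#'
#' @param x,y numeric arrays of identical shape.
#' @param max_val peak signal value (1 for pixels in `[0,1]`).
#' @return PSNR in decibels.
#' @export
psnr <- function(x, y, max_val = 1) {
  if (length(x) != length(y) || !identical(dim(x), dim(y)))
    stop("x and y must have identical shapes")
  stopifnot(max_val > 0)
  mse <- mean((x - y)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_val^2 / mse)
}

# separable valid-region Gaussian blur operator for an H-row image
.gauss_op <- function(H, window, sigma) {
  half <- (window - 1) / 2
  w <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- w / sum(w)
  Ho <- H - window + 1L
  G <- matrix(0, Ho, H)
  for (i in seq_len(Ho)) G[i, i:(i + window - 1L)] <- w
  G
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over an 11x11 Gaussian-weighted window (sigma 1.5),
#' computed on the valid (non-padded) region, with the standard stabilising
#' constants `C1 = (K1 L)^2`, `C2 = (K2 L)^2`. Symmetric in its arguments;
#' equals 1 only for identical inputs.
#'
#' @param x,y image matrices with equal dimensions, at least `window` pixels
#'   per side.
#' @param window odd window size.
#' @param sigma Gaussian window standard deviation.
#' @param K1,K2 stabilising constants.
#' @param L dynamic range of the pixel values (1 for `[0,1]` images).
#' @return scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(x, y, window = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 L = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (!identical(dim(x), dim(y))) stop("x and y must have identical shapes")
  if (nrow(x) < window || ncol(x) < window)
    stop("images must measure at least ", window, " pixels per side")
  Gr <- .gauss_op(nrow(x), window, sigma)
  Gc <- t(.gauss_op(ncol(x), window, sigma))
  blur <- function(m) Gr %*% m %*% Gc
  mx <- blur(x); my <- blur(y)
  sxx <- blur(x * x) - mx * mx
  syy <- blur(y * y) - my * my
  sxy <- blur(x * y) - mx * my
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  smap <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(smap)
}

# rank-based AUC (equivalent to the Wilcoxon statistic)
.auc_rank <- function(scores, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# average precision (step-wise integral of the precision-recall curve)
.average_precision <- function(scores, y) {
  n1 <- sum(y == 1L)
  if (n1 == 0L) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  cum_tp <- cumsum(ys)
  prec <- cum_tp / seq_along(ys)
  sum(prec[ys == 1L]) / n1
}

#' Downstream task utility of (possibly obfuscated) features
#'
#' Fits a classifier on the training features and reports accuracy, positive
#' class F1, AUC-ROC and average precision on the untouched test set.
#' Defaults: gradient-boosted trees (xgboost) for tabular features, an
#' L2-regularised linear probe (glmnet) for latents, images or other
#' high-dimensional representations.
#'
#' @param train_x,train_y training features (matrix, samples in rows) and
#'   binary labels.
#' @param test_x,test_y untouched evaluation features and labels.
#' @param classifier `"auto"`, `"xgboost"` or `"linear"`.
#' @param seed classifier seed.
#' @param nrounds boosting rounds for xgboost.
#' @param lambda ridge penalty for the linear probe.
#' @return a `utility_report`: accuracy, f1, auc, average_precision, n_eval,
#'   the test-set `scores`, plus `f1_degenerate` flagging the zero-division
#'   convention (no positive predictions and no true positives -> F1 = 0).
#' @export
downstream_utility <- function(train_x, train_y, test_x, test_y,
                               classifier = c("auto", "xgboost", "linear"),
                               seed = 1L, nrounds = 50L, lambda = 0.05) {
  classifier <- match.arg(classifier)
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (length(unique(train_y)) < 2L)
    stop("training labels contain a single class")
  if (nrow(test_x) == 0L) stop("test set is empty")
  if (classifier == "auto")
    classifier <- if (ncol(train_x) <= 64L) "xgboost" else "linear"
  scores <- if (classifier == "xgboost") {
    bst <- with_seed(seed, xgboost::xgboost(
      train_x, factor(train_y, levels = c(0, 1)), nrounds = nrounds,
      verbosity = 0, nthread = 1L, max_depth = 4L, learning_rate = 0.3))
    as.numeric(predict(bst, test_x, type = "response"))
  } else {
    fit <- glmnet::glmnet(train_x, factor(train_y), family = "binomial",
                          alpha = 0, lambda = lambda, standardize = TRUE)
    as.numeric(predict(fit, test_x, type = "response"))
  }
  pred <- as.integer(scores > 0.5)
  acc <- mean(pred == test_y)
  tp <- sum(pred == 1L & test_y == 1L)
  fp <- sum(pred == 1L & test_y == 0L)
  fn <- sum(pred == 0L & test_y == 1L)
  degenerate <- (2L * tp + fp + fn) == 0L  # no positive predictions, no positives
  f1 <- if (degenerate) 0 else 2 * tp / (2 * tp + fp + fn)
  structure(list(accuracy = acc, f1 = f1,
                 auc = .auc_rank(scores, test_y),
                 average_precision = .average_precision(scores, test_y),
                 n_eval = length(test_y), classifier = classifier,
                 f1_degenerate = degenerate, scores = scores),
            class = "utility_report")
}

#' @export
print.utility_report <- function(x, ...) {
  cat("Downstream utility (", x$classifier, ", n_eval = ", x$n_eval, ")\n",
      sep = "")
  cat(sprintf("  accuracy %.4f | F1 %.4f | AUC %.4f | AP %.4f\n",
              x$accuracy, x$f1, x$auc, x$average_precision))
  if (isTRUE(x$f1_degenerate))
    cat("  note: no positive predictions and no true positives; F1 set to 0\n")
  invisible(x)
}

#' Group-fairness gaps of a classifier
#'
#' Demographic parity gap `|P(yhat=1 | g=0) - P(yhat=1 | g=1)|` and equal
#' opportunity gap `|TPR(g=0) - TPR(g=1)|`.
#'
#' @param pred_y predicted binary labels.
#' @param true_y true binary labels.
#' @param group group membership (two levels).
#' @return a `fairness_report` with both gaps.
#' @export
fairness_metrics <- function(pred_y, true_y, group) {
  stopifnot(length(pred_y) == length(true_y),
            length(true_y) == length(group))
  gl <- sort(unique(group))
  if (length(gl) != 2L)
    stop("exactly two groups are required; got ", length(gl))
  g0 <- group == gl[1L]; g1 <- group == gl[2L]
  dp <- abs(mean(pred_y[g0] == 1L) - mean(pred_y[g1] == 1L))
  if (!any(true_y[g0] == 1L) || !any(true_y[g1] == 1L))
    stop("equal opportunity is undefined: a group has no positive outcomes")
  tpr0 <- mean(pred_y[g0 & true_y == 1L] == 1L)
  tpr1 <- mean(pred_y[g1 & true_y == 1L] == 1L)
  structure(list(demographic_parity_gap = dp,
                 equal_opportunity_gap = abs(tpr0 - tpr1)),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat(sprintf("Fairness gaps: demographic parity %.4f | equal opportunity %.4f\n",
              x$demographic_parity_gap, x$equal_opportunity_gap))
  invisible(x)
}
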
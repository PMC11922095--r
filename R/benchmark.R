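# Benchmark harness: run raw data, LSP and the baseline obfuscators through
# the same train/attack/evaluate protocol and assemble a comparison table
# plus privacy-utility curves.
#
# Protocol (identical for every method): the obfuscator transforms the
# training split; a downstream classifier is fitted on the transformed
# training data and evaluated on the untouched test split; the
# attribute-inference attacker is trained and evaluated on the released
# representation of the training split (z_ns for LSP, transformed features
# for the others, raw features for "raw"); image fidelity compares the
# released training images with the originals.

#' Benchmark configuration
#'
#' @param dataset an [image_gen_config()], [tabular_gen_config()] or a
#'   ready-made `lsp_dataset`.
#' @param methods named list of methods to run with their parameter grids:
#'   `raw = list()`, `lsp = list(gamma = c(...))`,
#'   `k_same = list(k = c(...))` (image), `k_anon = list(k = c(...))`
#'   (tabular), `dp = list(epsilon = c(...))`. A `raw` reference row is
#'   always added.
#' @param split_fraction train fraction of the train/test split.
#' @param seeds integer vector; every method/parameter combination is
#'   replicated once per seed.
#' @param lsp_epochs,lsp_batch_size training budget of the LSP runs.
#' @param attack an [attack_config()].
#' @param dp_delta,dp_clip Gaussian-mechanism parameters shared across its
#'   epsilon grid.
#' @param fidelity_n number of images used for the PSNR/SSIM summary.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(dataset, methods = list(raw = list()),
                             split_fraction = 0.8, seeds = c(1L, 2L, 3L),
                             lsp_epochs = 20L, lsp_batch_size = 64L,
                             attack = attack_config(),
                             dp_delta = 1e-5, dp_clip = 1,
                             fidelity_n = 100L) {
  if (!length(methods)) stop("at least one method is required")
  if (!length(seeds)) stop("at least one seed is required")
  if (!("raw" %in% names(methods))) methods <- c(list(raw = list()), methods)
  structure(list(dataset = dataset, methods = methods,
                 split_fraction = split_fraction, seeds = as.integer(seeds),
                 lsp_epochs = as.integer(lsp_epochs),
                 lsp_batch_size = as.integer(lsp_batch_size),
                 attack = attack, dp_delta = dp_delta, dp_clip = dp_clip,
                 fidelity_n = as.integer(fidelity_n)),
            class = "benchmark_config")
}

.bench_dataset <- function(dataset, seed) {
  if (inherits(dataset, "lsp_dataset")) return(dataset)
  cfg <- dataset
  cfg$seed <- cfg$seed + seed
  if (inherits(cfg, "image_gen_config")) generate_images(cfg)
  else if (inherits(cfg, "tabular_gen_config")) generate_transactions(cfg)
  else stop("dataset must be a generator config or an lsp_dataset")
}

# one benchmark row; returns a list of measurements
.bench_row <- function(method, param, split, config, seed) {
  train <- split$train; test <- split$test
  is_image <- train$modality == "image"
  released_train <- NULL   # what the data holder publishes
  test_features <- test$x  # representation the downstream model consumes at test time
  fit <- NULL
  if (method == "raw") {
    released_train <- train$x
  } else if (method == "lsp") {
    fit <- lsp(train, gamma = param, epochs = config$lsp_epochs,
               batch_size = config$lsp_batch_size, seed = seed)
    released_train <- predict(fit, train, type = "z_ns")
    test_features <- predict(fit, test, type = "z_ns")
  } else if (method == "k_same") {
    released_train <- k_same_images(train, k = param, seed = seed)
  } else if (method == "k_anon") {
    released_train <- as.matrix(k_anonymize_table(train$x, k = param))
  } else if (method == "dp") {
    released_train <- dp_gaussian_mechanism(
      train, dp_config(epsilon = param, delta = config$dp_delta,
                       clip = config$dp_clip, seed = seed))
  } else stop("unknown method: ", method)

  util <- downstream_utility(released_train, train$y, test_features, test$y,
                             seed = seed)
  att <- attribute_inference_attack(released_train, train$s,
                                    config = config$attack, seed = seed)
  fid <- NULL
  if (is_image && method != "lsp") {
    m <- min(config$fidelity_n, nrow(train$x))
    sz <- train$image_size
    ps <- vapply(seq_len(m), function(i)
      psnr(train$x[i, ], released_train[i, ]), 0)
    ss <- vapply(seq_len(m), function(i)
      ssim(matrix(train$x[i, ], sz, sz),
           matrix(released_train[i, ], sz, sz)), 0)
    fid <- list(psnr = mean(ps), ssim = mean(ss))
  } else if (is_image) {
    m <- min(config$fidelity_n, nrow(train$x))
    sz <- train$image_size
    obf <- predict(fit, dataset_subset(train, seq_len(m)), type = "obfuscated")
    ps <- vapply(seq_len(m), function(i) psnr(train$x[i, ], obf[i, ]), 0)
    ss <- vapply(seq_len(m), function(i)
      ssim(matrix(train$x[i, ], sz, sz), matrix(obf[i, ], sz, sz)), 0)
    fid <- list(psnr = mean(ps), ssim = mean(ss))
  }
  list(utility = util, privacy = att$report, fidelity = fid)
}

#' Run a privacy-utility benchmark
#'
#' Executes every configured method/parameter/seed combination through the
#' shared protocol and assembles one row per run; failures are captured per
#' row and the remaining runs continue.
#'
#' @param config a [benchmark_config()].
#' @return a `benchmark_report`: `rows` (data.frame with utility and privacy
#'   metrics per run), `aggregate` (mean and sd over seeds) and the config.
#' @export
run_benchmark <- function(config) {
  stopifnot(inherits(config, "benchmark_config"))
  rows <- list()
  for (seed in config$seeds) {
    data <- .bench_dataset(config$dataset, seed)
    split <- train_test_split(data, config$split_fraction, seed = seed)
    test_hash <- sum(split$test$x)
    for (method in names(config$methods)) {
      grid <- config$methods[[method]]
      params <- if (length(grid)) grid[[1L]] else NA_real_
      for (param in params) {
        res <- tryCatch(
          .bench_row(method, param, split, config, seed),
          error = function(e) e)
        failed <- inherits(res, "error")
        stopifnot(sum(split$test$x) == test_hash)  # test data never touched
        rows[[length(rows) + 1L]] <- data.frame(
          method = method,
          param = if (is.na(param)) NA_real_ else param,
          seed = seed,
          accuracy = if (failed) NA_real_ else res$utility$accuracy,
          f1 = if (failed) NA_real_ else res$utility$f1,
          auc = if (failed) NA_real_ else res$utility$auc,
          average_precision = if (failed) NA_real_ else res$utility$average_precision,
          attack_accuracy = if (failed) NA_real_ else res$privacy$attack_accuracy,
          chance_rate = if (failed) NA_real_ else res$privacy$chance_rate,
          protection_pct = if (failed) NA_real_ else res$privacy$protection_pct,
          psnr = if (failed || is.null(res$fidelity)) NA_real_ else res$fidelity$psnr,
          ssim = if (failed || is.null(res$fidelity)) NA_real_ else res$fidelity$ssim,
          failed = failed,
          message = if (failed) conditionMessage(res) else "")
      }
    }
  }
  rows <- do.call(rbind, rows)
  ok <- rows[!rows$failed, , drop = FALSE]
  key <- paste(ok$method, ifelse(is.na(ok$param), "", ok$param))
  aggregate <- do.call(rbind, lapply(split(ok, key), function(g) {
    data.frame(method = g$method[1L], param = g$param[1L], n_seeds = nrow(g),
               accuracy_mean = mean(g$accuracy), accuracy_sd = stats::sd(g$accuracy),
               protection_mean = mean(g$protection_pct),
               protection_sd = stats::sd(g$protection_pct))
  }))
  rownames(aggregate) <- NULL
  structure(list(rows = rows, aggregate = aggregate, config = config),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Privacy-utility benchmark (", sum(!x$rows$failed), " runs, ",
      sum(x$rows$failed), " failed)\n", sep = "")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    lbl <- if (is.na(agg$param[i])) agg$method[i]
           else paste0(agg$method[i], "(", agg$param[i], ")")
    cat(sprintf("  %-14s accuracy %.3f +/- %.3f | protection %5.1f +/- %.1f\n",
                lbl, agg$accuracy_mean[i],
                ifelse(is.na(agg$accuracy_sd[i]), 0, agg$accuracy_sd[i]),
                agg$protection_mean[i],
                ifelse(is.na(agg$protection_sd[i]), 0, agg$protection_sd[i])))
  }
  invisible(x)
}

#' Privacy-utility curve and its area
#'
#' Collects one point per parameter setting of a method (mean utility vs
#' mean protection over seeds, both normalised to `[0, 1]`), sorts by
#' protection and returns the trapezoidal area under the interpolated
#' utility-vs-protection curve over the observed protection range.
#'
#' @param report a `benchmark_report`, or a data.frame/list with numeric
#'   `protection` and `utility` columns already normalised to `[0, 1]`.
#' @param method method whose parameter grid forms the curve (ignored when
#'   points are supplied directly).
#' @return list with `points` (sorted) and `auc`.
#' @export
privacy_utility_curve <- function(report, method = "lsp") {
  if (inherits(report, "benchmark_report")) {
    agg <- report$aggregate
    agg <- agg[agg$method == method, , drop = FALSE]
    pts <- data.frame(protection = agg$protection_mean / 100,
                      utility = agg$accuracy_mean)
  } else {
    report <- as.data.frame(report)
    pts <- data.frame(protection = report$protection,
                      utility = report$utility)
  }
  if (nrow(pts) < 2L)
    stop("at least two parameter points are required for a curve")
  pts <- pts[order(pts$protection), , drop = FALSE]
  x <- pts$protection; y <- pts$utility
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  list(points = pts, auc = auc)
}
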
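# Comparison obfuscators: Mondrian-style k-anonymity for tables, k-Same
# centroid averaging for images, and the classical Gaussian mechanism of
# (epsilon, delta)-differential privacy.

#' k-anonymise a table by Mondrian-style generalisation
#'
#' Recursively partitions the rows on the quasi-identifier columns (widest
#' normalised range first, median cut, lower median to the left), stopping
#' when a further cut would leave a side with fewer than `k` rows, then
#' replaces each quasi-identifier value by the midpoint of its leaf interval.
#' Every equivalence class (distinct quasi-identifier tuple) in the output
#' therefore contains at least `k` rows.
#'
#' @param table data.frame or matrix with numeric quasi-identifier columns.
#' @param k minimum equivalence-class size (`k = 1` returns the input).
#' @param quasi_identifiers column names or indices to generalise; default
#'   all numeric columns.
#' @return the table with generalised quasi-identifiers.
#' @export
k_anonymize_table <- function(table, k = 5L, quasi_identifiers = NULL) {
  df <- as.data.frame(table)
  stopifnot(k >= 1L)
  if (is.null(quasi_identifiers))
    quasi_identifiers <- names(df)[vapply(df, is.numeric, TRUE)]
  if (length(quasi_identifiers) == 0L) stop("quasi_identifiers is empty")
  qi <- if (is.numeric(quasi_identifiers)) names(df)[quasi_identifiers]
        else quasi_identifiers
  if (!all(qi %in% names(df))) stop("unknown quasi-identifier column")
  if (k == 1L) return(df)
  n <- nrow(df)
  Q <- as.matrix(df[, qi, drop = FALSE])
  rng <- apply(Q, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  if (n < k) {
    warning("fewer rows than k; all quasi-identifiers fully suppressed ",
            "into a single class")
    for (j in seq_along(qi)) df[[qi[j]]] <- mean(range(Q[, j]))
    return(df)
  }
  out <- Q
  recurse <- function(rows) {
    if (length(rows) < 2L * k) {
      for (j in seq_len(ncol(Q)))
        out[rows, j] <<- mean(range(Q[rows, j]))
      return(invisible())
    }
    # widest normalised range first; median cut with both sides >= k
    spread <- apply(Q[rows, , drop = FALSE], 2,
                    function(v) diff(range(v))) / rng
    for (j in order(spread, decreasing = TRUE)) {
      v <- Q[rows, j]
      o <- order(v)
      cut_at <- min(max(length(rows) %/% 2L, k), length(rows) - k)
      left <- rows[o[seq_len(cut_at)]]
      right <- rows[o[(cut_at + 1L):length(rows)]]
      # refuse a cut that does not separate values (ties across the cut)
      if (v[o[cut_at]] < v[o[cut_at + 1L]]) {
        recurse(left); recurse(right)
        return(invisible())
      }
    }
    for (j in seq_len(ncol(Q)))
      out[rows, j] <<- mean(range(Q[rows, j]))
    invisible()
  }
  recurse(seq_len(n))
  for (j in seq_along(qi)) df[[qi[j]]] <- out[, j]
  df
}

#' k-Same image de-identification
#'
#' Greedy nearest-neighbour grouping in pixel space: images are visited in a
#' seeded random order, each unassigned image collects its `k - 1` nearest
#' unassigned neighbours, and every image is replaced by its cluster mean.
#' Remaining images (fewer than `k`) join their nearest cluster, so each
#' output image is shared by at least `k` inputs and the number of distinct
#' outputs is at most `floor(n / k)`.
#'
#' @param images matrix with one flattened image per row, or an image
#'   `lsp_dataset`.
#' @param k minimum group size (`k = 1` returns the input; `k = n` yields
#'   the global mean image).
#' @param seed seed for the visiting order.
#' @return matrix of de-identified images (same shape as input).
#' @export
k_same_images <- function(images, k = 5L, seed = 1L) {
  X <- if (inherits(images, "lsp_dataset")) images$x else as.matrix(images)
  n <- nrow(X)
  stopifnot(k >= 1L)
  if (k == 1L) return(X)
  if (n < k) {
    warning("fewer images than k; returning the global mean for all images")
    return(matrix(colMeans(X), n, ncol(X), byrow = TRUE))
  }
  order_all <- with_seed(seed, sample.int(n))
  cluster <- integer(n)
  n_clusters <- 0L
  sq <- rowSums(X * X)
  for (i in order_all) {
    if (cluster[i] != 0L) next
    free <- which(cluster == 0L)
    if (length(free) < k) break
    d2 <- sq[free] - 2 * drop(X[free, , drop = FALSE] %*% X[i, ])
    members <- free[order(d2)][seq_len(k)]
    n_clusters <- n_clusters + 1L
    cluster[members] <- n_clusters
  }
  centroids <- t(vapply(seq_len(n_clusters), function(cl)
    colMeans(X[cluster == cl, , drop = FALSE]), numeric(ncol(X))))
  left <- which(cluster == 0L)
  if (length(left)) {
    cs <- rowSums(centroids * centroids)
    for (i in left) {
      d2 <- cs - 2 * drop(centroids %*% X[i, ])
      cluster[i] <- which.min(d2)
    }
    for (cl in unique(cluster[left]))
      centroids[cl, ] <- colMeans(X[cluster == cl, , drop = FALSE])
  }
  centroids[cluster, , drop = FALSE]
}

#' Gaussian-mechanism configuration
#'
#' @param epsilon privacy budget, `> 0`.
#' @param delta failure probability, in `(0, 1)`.
#' @param clip sensitivity bound: tabular values are clipped to
#'   `[-clip, clip]`; image pixels are clipped to `[0, 1]` (range `clip`).
#' @param seed noise seed.
#' @return list of class `dp_config`.
#' @export
dp_config <- function(epsilon = 1, delta = 1e-5, clip = 1, seed = 1L) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  if (delta <= 0 || delta >= 1) stop("delta must lie in (0, 1)")
  if (clip <= 0) stop("clip must be > 0")
  structure(list(epsilon = epsilon, delta = delta, clip = clip,
                 seed = as.integer(seed)), class = "dp_config")
}

#' Gaussian-mechanism noise scale
#'
#' The classical calibration `sigma = clip * sqrt(2 * log(1.25 / delta)) /
#' epsilon`.
#'
#' @param epsilon,delta,clip mechanism parameters (see [dp_config()]).
#' @return the noise standard deviation.
#' @export
dp_sigma <- function(epsilon, delta, clip = 1) {
  clip * sqrt(2 * log(1.25 / delta)) / epsilon
}

#' Apply the Gaussian mechanism of differential privacy
#'
#' Values are clipped to the sensitivity bound, independent Gaussian noise
#' with the classical scale [dp_sigma()] is added, and image pixels are
#' re-clipped to `[0, 1]`.
#'
#' @param x numeric matrix (samples in rows) or an `lsp_dataset`.
#' @param config a [dp_config()].
#' @param image treat values as pixels in `[0, 1]` (clip there before and
#'   after noising); default auto-detected from an `lsp_dataset`.
#' @return noised matrix of the same shape.
#' @export
dp_gaussian_mechanism <- function(x, config = dp_config(), image = NULL) {
  stopifnot(inherits(config, "dp_config"))
  if (inherits(x, "lsp_dataset")) {
    if (is.null(image)) image <- x$modality == "image"
    x <- x$x
  }
  if (is.null(image)) image <- FALSE
  x <- as.matrix(x)
  if (image) {
    x[x < 0] <- 0; x[x > 1] <- 1
  } else {
    x[x < -config$clip] <- -config$clip
    x[x > config$clip] <- config$clip
  }
  sigma <- dp_sigma(config$epsilon, config$delta, config$clip)
  out <- x + with_seed(config$seed,
                       matrix(stats::rnorm(length(x), sd = sigma),
                              nrow(x), ncol(x)))
  if (image) {
    out[out < 0] <- 0; out[out > 1] <- 1
  }
  out
}
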
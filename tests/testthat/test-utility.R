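# PSNR/SSIM fidelity metrics, downstream classification metrics against
# brute-force and library oracles, and fairness gaps.

test_that("psnr matches its closed form", {
  x <- matrix(runif(64), 8, 8)
  expect_identical(psnr(x, x), Inf)
  y <- x + 0.1
  expect_equal(psnr(x, y), 20, tolerance = 1e-9)
  z <- matrix(runif(64), 8, 8)
  expect_equal(psnr(x, z), 10 * log10(1 / mean((x - z)^2)), tolerance = 1e-9)
  expect_error(psnr(x, matrix(0, 4, 16)), "identical shapes")
})

test_that("psnr decreases as noise grows", {
  x <- matrix(runif(400), 20, 20)
  vals <- vapply(c(0.01, 0.05, 0.1, 0.2), function(sd) {
    mean(vapply(1:5, function(r) {
      set.seed(r)
      psnr(x, pmin(pmax(x + rnorm(400, sd = sd), 0), 1))
    }, 0))
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("ssim identity, symmetry, bounds and cross-implementation value", {
  set.seed(123)
  x <- matrix(runif(256), 16, 16)
  y <- pmin(pmax(0.7 * x + 0.3 * matrix(runif(256), 16, 16), 0), 1)
  expect_equal(ssim(x, x), 1, tolerance = 1e-12)
  expect_equal(ssim(x, y), ssim(y, x), tolerance = 1e-12)
  expect_true(ssim(x, y) >= -1 && ssim(x, y) <= 1)
  expect_lt(ssim(x, y), 1)
  # frozen value from an independent explicit-window implementation
  expect_equal(ssim(x, y), 0.8709044728, tolerance = 1e-6)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "at least 11")
})

test_that("downstream utility handles separable and degenerate cases", {
  set.seed(17)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  x <- cbind(y * 4 + rnorm(n, sd = 0.2), matrix(rnorm(n * 3), n, 3))
  rep <- downstream_utility(x[1:300, ], y[1:300], x[301:400, ], y[301:400],
                            classifier = "xgboost", seed = 1)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$auc, 1)

  # unlearnable rare positives: the model predicts all-negative, F1 = 0
  y2 <- c(rep(0, 280), rep(1, 20))[sample(300)]
  x2 <- matrix(rnorm(300 * 4), 300, 4)
  rep2 <- downstream_utility(x2[1:200, ], y2[1:200], x2[201:300, ],
                             y2[201:300], classifier = "linear", seed = 1)
  expect_equal(rep2$f1, 0)

  expect_error(downstream_utility(x2[1:50, ], rep(0, 50), x2, y2),
               "single class")
})

test_that("classification metrics agree with brute-force and pROC oracles", {
  set.seed(18)
  n <- 500
  y <- rbinom(n, 1, 0.4)
  x <- cbind(y + rnorm(n), matrix(rnorm(n * 2), n, 2))
  tr <- 1:350; te <- 351:500
  rep <- downstream_utility(x[tr, ], y[tr], x[te, ], y[te],
                            classifier = "xgboost", seed = 2)
  scores <- rep$scores
  pred <- as.integer(scores > 0.5)
  # accuracy / F1 by explicit confusion-matrix counting
  tp <- sum(pred == 1 & y[te] == 1); fp <- sum(pred == 1 & y[te] == 0)
  fn <- sum(pred == 0 & y[te] == 1); tn <- sum(pred == 0 & y[te] == 0)
  expect_equal(rep$accuracy, (tp + tn) / length(te))
  expect_equal(rep$f1, 2 * tp / (2 * tp + fp + fn))
  # AUC against pROC
  skip_if_not_installed("pROC")
  expect_equal(rep$auc,
               as.numeric(pROC::auc(pROC::roc(y[te], scores, quiet = TRUE))),
               tolerance = 1e-10)
  # average precision by brute-force loop over positive ranks
  o <- order(scores, decreasing = TRUE)
  ys <- y[te][o]
  ap <- 0; seen <- 0
  for (i in seq_along(ys)) {
    if (ys[i] == 1) { seen <- seen + 1; ap <- ap + seen / i }
  }
  expect_equal(rep$average_precision, ap / sum(ys), tolerance = 1e-12)
})

test_that("fairness gaps match direct group computations", {
  pred <- c(1, 1, 1, 0, 0, 1, 0, 0, 0, 0)
  truth <- c(1, 1, 0, 1, 0, 1, 0, 1, 0, 0)
  grp <- rep(c(0, 1), each = 5)
  rep <- fairness_metrics(pred, truth, grp)
  expect_equal(rep$demographic_parity_gap, abs(3 / 5 - 1 / 5))
  expect_equal(rep$equal_opportunity_gap,
               abs(mean(pred[grp == 0 & truth == 1]) -
                   mean(pred[grp == 1 & truth == 1])))
  # identical prediction rates: both gaps zero
  rep0 <- fairness_metrics(rep(c(1, 0), 6), rep(c(1, 0), 6),
                           rep(c(0, 1), each = 6))
  expect_equal(rep0$demographic_parity_gap, 0)
  expect_equal(rep0$equal_opportunity_gap, 0)
  # random case equals brute force
  set.seed(19)
  p <- rbinom(60, 1, 0.5); t2 <- rbinom(60, 1, 0.5); g <- rbinom(60, 1, 0.5)
  if (any(t2[g == 0] == 1) && any(t2[g == 1] == 1)) {
    rp <- fairness_metrics(p, t2, g)
    expect_equal(rp$demographic_parity_gap,
                 abs(mean(p[g == 0]) - mean(p[g == 1])))
  }
  expect_error(fairness_metrics(pred, truth, rep(0, 10)), "two groups")
  expect_error(fairness_metrics(c(0, 1), c(0, 0), c(0, 1)), "no positive")
})
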
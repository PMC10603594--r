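test_that("single-predictor PLS equals the closed-form least-squares slope", {
  set.seed(1)
  p <- runif(100)
  y <- 3 * p + rnorm(100, sd = 0.2)
  fit <- fit_pls(matrix(p, ncol = 1), y, a = 1)
  slope_ols <- sum((p - mean(p)) * (y - mean(y))) / sum((p - mean(p))^2)
  expect_equal(unname(fit$coefficients), slope_ols, tolerance = 1e-8)
  expect_equal(fit$intercept, mean(y) - slope_ols * mean(p), tolerance = 1e-8)
})

test_that("a response equal to a predictor column is fit perfectly", {
  set.seed(2)
  P <- matrix(runif(200), 50, 4)
  y <- P[, 2]
  fit <- fit_pls(P, y, a = 4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(predict_pls(fit, P)), y, tolerance = 1e-8)
})

test_that("x-scores are mutually orthogonal", {
  set.seed(3)
  P <- matrix(runif(300), 60, 5)
  y <- P %*% runif(5) + rnorm(60, sd = 0.1)
  fit <- fit_pls(P, y, a = 4)
  G <- crossprod(fit$x_scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("PLS coefficients agree with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(4)
  P <- matrix(runif(240), 60, 4, dimnames = list(NULL, paste0("p", 1:4)))
  y <- 2 * P[, 1] - P[, 3] + rnorm(60, sd = 0.3)
  mine <- fit_pls(P, y, a = 2)
  ref <- mixOmics::pls(P, y, ncomp = 2, mode = "regression",
                       scale = FALSE)
  pred_ref <- predict(ref, P)$predict[, 1, 2]
  expect_equal(unname(mine$fitted), unname(pred_ref), tolerance = 1e-6)
})

test_that("VIP scores satisfy the sum-of-squares identity", {
  set.seed(5)
  for (i in 1:5) {
    s <- sample(3:15, 1)
    P <- matrix(runif(40 * s), 40, s)
    y <- P %*% rnorm(s) + rnorm(40, sd = 0.2)
    fit <- fit_pls(P, y, a = min(3, s - 1))
    expect_equal(sum(vip_scores(fit)^2), s, tolerance = 1e-8)
  }
})

test_that("VIP singles out the relevant predictor among noise", {
  fx <- make_sparse_pls_dataset(n = 150, s = 10, support = 4, beta = 2,
                                noise_sd = 0.1, seed = 6)
  fit <- fit_pls(fx$P, fx$y, a = 2)
  v <- vip_scores(fit)
  expect_gt(v[4], 1)
  expect_true(all(v[-4] < v[4]))
})

test_that("coefficient ranking orders by magnitude and keeps signs", {
  fake <- structure(list(coefficients = c(a = 0.1, b = -0.5, c = 0.2)),
                    class = "pls_model")
  r <- coefficient_ranking(fake)
  expect_equal(r$param, c("b", "c", "a"))
  expect_equal(r$sign, c("-", "+", "+"))
  # on a generative fixture the true support is ranked first with true signs
  fx <- make_sparse_pls_dataset(n = 200, s = 8, support = c(2, 5),
                                beta = c(3, -2), noise_sd = 0.05, seed = 7)
  fit <- fit_pls(fx$P, fx$y, a = 2)
  r2 <- coefficient_ranking(fit)
  expect_setequal(r2$param[1:2], c("p2", "p5"))
  expect_equal(r2$sign[r2$param == "p2"], "+")
  expect_equal(r2$sign[r2$param == "p5"], "-")
})

test_that("per-class refits are tighter than the pooled fit", {
  fx <- make_two_blob_dataset(n_per_class = 80, separation = 8, noise = 1,
                              m = 3, s = 6, seed = 8)
  pc1 <- fit_pca(fx$X, r = 1)$scores[, 1]
  pooled <- fit_pls(fx$P, pc1, a = 2)
  per <- per_class_refit(fx$P, pc1, fx$labels, a = 2)
  rss_pooled <- sum((pc1 - pooled$fitted)^2)
  rss_per <- sum(vapply(names(per), function(cl) {
    idx <- fx$labels == as.integer(cl)
    sum((pc1[idx] - per[[cl]]$fitted)^2)
  }, 0))
  expect_lt(rss_per, rss_pooled)
  # identical data per class -> identical refits
  P2 <- rbind(fx$P[1:20, ], fx$P[1:20, ])
  y2 <- c(pc1[1:20], pc1[1:20])
  lab2 <- rep(1:2, each = 20)
  per2 <- per_class_refit(P2, y2, lab2, a = 1)
  expect_equal(per2[["1"]]$coefficients, per2[["2"]]$coefficients)
  expect_error(per_class_refit(fx$P[1:4, ], pc1[1:4], c(1, 1, 1, 2), a = 2),
               "class")
})

test_that("classification rule achieves perfect accuracy on disjoint classes", {
  # parameters with a hard margin -> fitted-value supports are disjoint
  set.seed(9)
  P <- cbind(c(runif(100, 0, 0.4), runif(100, 0.6, 1)), runif(200))
  labels <- rep(1:2, each = 100)
  y <- ifelse(labels == 1, -1, 1) + rnorm(200, sd = 0.05)
  tr <- train_test_split(labels, 0.7, seed = 10)
  fit <- fit_pls(P[tr, ], y[tr], a = 2)
  rule <- build_rule(fit, labels[tr], ci_levels = c(0.90, 0.95, 0.99))
  rep <- evaluate_rule(rule, P[!tr, ], labels[!tr])
  expect_true(all(rep$accuracy == 1))
})

test_that("widening the confidence level never loses true classifications", {
  fx <- make_two_blob_dataset(n_per_class = 100, separation = 6, noise = 1,
                              seed = 11)
  pc1 <- fit_pca(fx$X, r = 1)$scores[, 1]
  tr <- train_test_split(fx$labels, 0.7, seed = 12)
  fit <- fit_pls(fx$P[tr, ], pc1[tr], a = 2)
  for (type in c("gaussian", "quantile")) {
    rule <- build_rule(fit, fx$labels[tr],
                       ci_levels = c(0.80, 0.90, 0.95, 0.99),
                       interval_type = type)
    rep <- as.data.frame(evaluate_rule(rule, fx$P[!tr, ], fx$labels[!tr]))
    for (cl in unique(rep$class)) {
      tr_counts <- rep$n_true[rep$class == cl]
      expect_true(all(diff(tr_counts) >= 0))
    }
  }
})

test_that("rule construction rejects degenerate class structures", {
  fit <- structure(list(fitted = rep(1:2, each = 10)), class = "pls_model")
  expect_error(build_rule(fit, rep(1, 20)), "2 classes")
  expect_error(build_rule(fit, rep(c(1, 2), 10)), "identical")
})

test_that("empty test classes are reported as undefined, not errors", {
  fx <- make_two_blob_dataset(n_per_class = 30, separation = 10, seed = 13)
  pc1 <- fit_pca(fx$X, r = 1)$scores[, 1]
  fit <- fit_pls(fx$P, pc1, a = 1)
  rule <- build_rule(fit, fx$labels, ci_levels = 0.95)
  only1 <- fx$labels == 1
  rep <- as.data.frame(evaluate_rule(rule, fx$P[only1, ], fx$labels[only1]))
  expect_true(is.na(rep$accuracy[rep$class == "2"]))
  expect_false(is.na(rep$accuracy[rep$class == "1"]))
})

test_that("train/test splits are stratified and disjoint", {
  labels <- rep(1:2, c(70, 30))
  tr <- train_test_split(labels, 0.70, seed = 14)
  expect_equal(sum(tr[labels == 1]), 49)
  expect_equal(sum(tr[labels == 2]), 21)
  tr2 <- train_test_split(labels, 0.70, seed = 14)
  expect_identical(tr, tr2)
})

test_that("min-max normalization maps intervals onto the unit cube", {
  iv <- rbind(c(2, 6), c(-1, 1), c(5, 5))
  P <- cbind(c(2, 4, 6), c(-1, 0, 1), c(5, 5, 5))
  N <- normalize_params(P, iv)
  expect_equal(N[, 1], c(0, 0.5, 1))
  expect_equal(N[, 2], c(0, 0.5, 1))
  expect_equal(N[, 3], rep(0.5, 3))  # degenerate column carries no signal
})
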
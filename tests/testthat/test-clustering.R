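test_that("well-separated blobs are recovered exactly", {
  fx <- make_two_blob_dataset(n_per_class = 60, separation = 10, noise = 1,
                              seed = 2)
  lab <- cluster_fates(fx$X, k = 2)
  # labels may be permuted; compare partitions
  tab <- table(lab$labels, fx$labels)
  expect_equal(sum(apply(tab, 1, max)), nrow(fx$X))
})

test_that("labels are renumbered by descending cluster size", {
  fx <- make_two_blob_dataset(n_per_class = 40, separation = 10, seed = 3)
  # drop some rows of one class to force unequal sizes
  keep <- c(which(fx$labels == 1), which(fx$labels == 2)[1:10])
  lab <- cluster_fates(fx$X[keep, ], k = 2)
  expect_true(lab$sizes[1] >= lab$sizes[2])
  expect_equal(sum(lab$sizes), length(keep))
})

test_that("clustering is invariant to row permutation", {
  fx <- make_two_blob_dataset(n_per_class = 30, separation = 8, seed = 4)
  lab <- cluster_fates(fx$X, k = 2)
  perm <- sample(nrow(fx$X))
  lab_p <- cluster_fates(fx$X[perm, ], k = 2)
  expect_equal(lab_p$labels, lab$labels[perm])
})

test_that("k out of range raises an error", {
  fx <- make_two_blob_dataset(n_per_class = 5, separation = 8, seed = 5)
  expect_error(cluster_fates(fx$X, k = 100), "exceeds")
  expect_error(cluster_fates(fx$X, k = 1), "at least 2")
})

test_that("toggle-switch fates coincide with protein dominance", {
  ts <- toggle_switch_model()
  smp <- sample_parameters(ts, 250, seed = 31)
  ds <- build_dataset(ts, smp)
  mono <- split_mono_multi(ds)$mono
  oracle <- ts_dominance(mono$X)
  for (std in c(FALSE, TRUE)) {
    lab <- cluster_fates(mono$X, k = 2, standardize = std)
    tab <- table(lab$labels, oracle)
    expect_gte(sum(apply(tab, 1, max)) / nrow(mono$X), 0.98)
  }
})

test_that("marker naming orders classes by expression", {
  fx <- make_two_blob_dataset(n_per_class = 30, separation = 8, seed = 6)
  lab <- cluster_fates(fx$X, k = 2)
  named <- name_fates_by_marker(lab, fx$X, marker = "x1",
                                names = c("low", "high"))
  means <- tapply(fx$X[, "x1"], lab$labels, mean)
  expect_equal(named$class_names[which.min(means)], "low")
  expect_equal(named$class_names[which.max(means)], "high")
})

test_that("hybrid filtering removes exactly hybrid-bearing parameter rows", {
  fx <- make_two_blob_dataset(n_per_class = 20, separation = 8, seed = 7)
  ds <- list(X = fx$X, row_to_param = seq_len(nrow(fx$X)),
             n_states_per_param = rep(1L, nrow(fx$X)),
             mono_mask = rep(TRUE, nrow(fx$X)),
             multi_mask = rep(FALSE, nrow(fx$X)),
             fate_labels = rep(NA_integer_, nrow(fx$X)),
             sample = list(P = fx$P, intervals = fx$intervals,
                           param_names = colnames(fx$P), seed = 1L),
             model_name = "fixture", n_failed = 0L)
  class(ds) <- "fate_dataset"
  # no hybrid flagged -> identity
  out <- filter_hybrid_for_em(ds, is_hybrid = rep(FALSE, nrow(fx$X)))
  expect_equal(out$X, ds$X)
  # a synthetic tristable row: states 1 to 3 share parameter row 1,
  # state 2 is hybrid -> all three states of that row must go
  ds3 <- ds
  ds3$row_to_param <- c(1L, 1L, 1L, seq(2L, nrow(fx$X) - 2L))
  hyb <- rep(FALSE, nrow(fx$X)); hyb[2] <- TRUE
  out3 <- filter_hybrid_for_em(ds3, is_hybrid = hyb)
  expect_false(1L %in% out3$row_to_param)
  expect_equal(nrow(out3$X), nrow(fx$X) - 3)
})

test_that("automatic hybrid identification flags the intermediate cloud", {
  set.seed(8)
  n <- 40
  X <- rbind(matrix(rnorm(n * 3, 0), ncol = 3),
             matrix(rnorm(n * 3, 5), ncol = 3),
             matrix(rnorm(n * 3, 10), ncol = 3))
  ds <- list(X = X, row_to_param = seq_len(3 * n),
             n_states_per_param = rep(1L, 3 * n),
             mono_mask = rep(TRUE, 3 * n), multi_mask = rep(FALSE, 3 * n),
             fate_labels = rep(NA_integer_, 3 * n),
             sample = list(P = matrix(0, 3 * n, 1), seed = 1L),
             model_name = "fixture", n_failed = 0L)
  class(ds) <- "fate_dataset"
  out <- filter_hybrid_for_em(ds)
  kept <- out$row_to_param
  # the middle cloud (rows n+1 .. 2n) is identified as hybrid and removed
  expect_equal(sum(kept > n & kept <= 2 * n), 0)
  expect_equal(length(kept), 2 * n)
})
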
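#' Two-blob labelled fate fixture
#'
#' Generates a statistical stand-in for a bistable system's monostable data:
#' two Gaussian state clouds in m dimensions whose membership is driven
#' linearly by the first `n_informative` parameter columns. Class 1 sits at
#' `-separation/2` and class 2 at `+separation/2` along the first state
#' axis (shared offset on the remaining axes), with isotropic `noise`.
#' Parameters are uniform on \[0, 1\]; the class is 2 when the mean of the
#' informative columns exceeds 1/2 (plus label noise proportional to
#' `noise / separation` when `separation` is small), so the parameter-to-
#' class map is learnable by linear rules.
#'
#' @param n_per_class States per class.
#' @param separation Distance between cloud centers along the first axis.
#' @param noise Within-cloud standard deviation.
#' @param m State dimension.
#' @param s Parameter dimension.
#' @param n_informative Number of class-informative parameter columns.
#' @param seed Seed; the fixture is bit-reproducible from it.
#' @return A list mimicking a solved dataset: `X` (states), `P`
#'   (parameters), `labels` (true class), `intervals`.
#' @export
make_two_blob_dataset <- function(n_per_class = 200, separation = 6,
                                  noise = 1, m = 2, s = 10,
                                  n_informative = 2, seed = 1L) {
  stopifnot(separation >= 0, n_informative <= s)
  n <- 2L * n_per_class
  with_seed(seed, {
    P <- matrix(runif(n * s), n, s,
                dimnames = list(NULL, paste0("p", seq_len(s))))
    score <- rowMeans(P[, seq_len(n_informative), drop = FALSE])
    labels <- ifelse(score > 0.5, 2L, 1L)
    # rebalance to exactly n_per_class per class by flipping the rows
    # nearest the boundary
    for (cl in 1:2) {
      excess <- sum(labels == cl) - n_per_class
      if (excess > 0) {
        idx <- which(labels == cl)
        flip <- idx[order(abs(score[idx] - 0.5))[seq_len(excess)]]
        labels[flip] <- 3L - cl
        # move their parameters across the boundary so labels stay learnable
        P[flip, seq_len(n_informative)] <-
          1 - P[flip, seq_len(n_informative), drop = FALSE]
      }
    }
    centers <- rbind(c(-separation / 2, rep(0, m - 1)),
                     c(+separation / 2, rep(0, m - 1)))
    X <- centers[labels, , drop = FALSE] + matrix(rnorm(n * m, sd = noise), n, m)
    colnames(X) <- paste0("x", seq_len(m))
    intervals <- cbind(low = rep(0, s), high = rep(1, s))
    rownames(intervals) <- colnames(P)
    list(X = X, P = P, labels = labels, intervals = intervals)
  })
}

#' Sparse linear parameter-to-response fixture
#'
#' `y = P[, support] %*% beta + noise`, the generative model used to test
#' support recovery by VIP scores and coefficient signs.
#'
#' @param n Rows.
#' @param s Parameter columns (uniform on \[0, 1\]).
#' @param support Indices of the truly active parameters.
#' @param beta Coefficients on the active parameters.
#' @param noise_sd Noise standard deviation (set from a target
#'   signal-to-noise ratio as `sd(signal)/sqrt(snr)`).
#' @param seed Seed.
#' @return List with `P`, `y`, `support`, `beta`.
#' @export
make_sparse_pls_dataset <- function(n = 200, s = 20, support = c(3, 7, 11),
                                    beta = c(2, -1.5, 1), noise_sd = 0.1,
                                    seed = 1L) {
  stopifnot(length(support) == length(beta), max(support) <= s)
  with_seed(seed, {
    P <- matrix(runif(n * s), n, s,
                dimnames = list(NULL, paste0("p", seq_len(s))))
    y <- as.numeric(P[, support, drop = FALSE] %*% beta) +
      rnorm(n, sd = noise_sd)
    list(P = P, y = y, support = support, beta = beta)
  })
}
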
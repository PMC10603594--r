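#' Min-max normalize parameters to the unit interval
#'
#' Maps each parameter column onto \[0, 1\] using its sampling interval, the
#' preprocessing applied before any regression on parameters. Degenerate
#' (fixed) parameters map to 0.5 and carry no information.
#'
#' @param P n x s parameter matrix.
#' @param intervals s x 2 matrix of (low, high) sampling bounds.
#' @return Matrix of the same shape with values in \[0, 1\].
#' @export
normalize_params <- function(P, intervals) {
  intervals <- as.matrix(intervals)
  width <- intervals[, 2] - intervals[, 1]
  out <- sweep(as.matrix(P), 2, intervals[, 1])
  out <- sweep(out, 2, ifelse(width > 0, width, 1), "/")
  out[, width == 0] <- 0.5
  out
}

#' Fit a partial least-squares regression (single response)
#'
#' NIPALS PLS1: predictors and response are centered, then `a` orthogonal
#' latent components are extracted, each maximizing covariance with the
#' residual response. Coefficients are returned on the (normalized) predictor
#' scale, so `fitted = intercept + P %*% coefficients`.
#'
#' @param P n x s predictor matrix (parameters, min-max normalized).
#' @param y Length-n response (typically PC1 scores of the steady states).
#' @param a Number of latent components (1 <= a < n). When `NULL`, chosen by
#'   5-fold cross-validation via [select_ncomp()].
#' @param cv_seed Seed for the cross-validation folds when `a` is `NULL`.
#' @return An object of class `pls_model`: `coefficients`, `intercept`,
#'   `x_weights` (s x a, unit columns), `x_loadings`, `y_loadings`,
#'   `x_scores` (training), `ss_comp` (response variance captured per
#'   component), `fitted`, `r_squared`, `ncomp`, `x_mean`, `y_mean`.
#' @export
fit_pls <- function(P, y, a = NULL, cv_seed = 1L) {
  P <- as.matrix(P)
  y <- as.numeric(y)
  stopifnot(nrow(P) == length(y))
  if (var(y) < .Machine$double.eps) stop("zero-variance response")
  if (is.null(a)) a <- select_ncomp(P, y, seed = cv_seed)
  stopifnot(a >= 1, a < nrow(P))

  x_mean <- colMeans(P)
  y_mean <- mean(y)
  X <- sweep(P, 2, x_mean)
  yr <- y - y_mean
  s <- ncol(P)
  W <- Pl <- matrix(0, s, a)
  Tm <- matrix(0, nrow(P), a)
  qv <- ss <- numeric(a)
  for (h in seq_len(a)) {
    w <- crossprod(X, yr)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) {  # response residual exhausted
      a <- h - 1L
      if (a == 0L) stop("predictors carry no covariance with the response")
      W <- W[, seq_len(a), drop = FALSE]; Pl <- Pl[, seq_len(a), drop = FALSE]
      Tm <- Tm[, seq_len(a), drop = FALSE]; qv <- qv[seq_len(a)]
      ss <- ss[seq_len(a)]
      break
    }
    w <- w / wn
    t <- X %*% w
    tt <- sum(t^2)
    p <- crossprod(X, t) / tt
    q <- sum(yr * t) / tt
    X <- X - t %*% t(p)
    yr <- yr - q * t
    W[, h] <- w; Pl[, h] <- p; Tm[, h] <- t; qv[h] <- q
    ss[h] <- q^2 * tt
  }
  R <- W %*% solve(crossprod(Pl, W))
  beta <- as.numeric(R %*% qv)
  fitted <- as.numeric(y_mean + sweep(P, 2, x_mean) %*% beta)
  structure(
    list(coefficients = setNames(beta, colnames(P)),
         intercept = y_mean - sum(x_mean * beta),
         x_weights = W, x_loadings = Pl, y_loadings = qv, x_scores = Tm,
         ss_comp = ss, fitted = fitted,
         r_squared = 1 - sum((y - fitted)^2) / sum((y - mean(y))^2),
         ncomp = a, x_mean = x_mean, y_mean = y_mean),
    class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$ncomp, " component(s), training R^2 = ",
      round(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' Predict the fitted response for new parameter sets
#' @param pls A [fit_pls()] model.
#' @param P_new Matrix on the same (normalized) predictor scale.
#' @return Numeric vector of fitted responses.
#' @export
predict_pls <- function(pls, P_new) {
  as.numeric(pls$intercept + as.matrix(P_new) %*% pls$coefficients)
}

#' Choose the number of PLS components by cross-validation
#'
#' 5-fold cross-validated prediction error, components capped at
#' `min(s, 10, n - 2)`; the smallest `a` within one percent of the best
#' RMSEP is selected to avoid overfitting noise components.
#'
#' @param P Predictor matrix.
#' @param y Response.
#' @param a_max Largest number of components to consider.
#' @param folds Number of folds.
#' @param seed Fold-assignment seed.
#' @return Integer number of components.
#' @export
select_ncomp <- function(P, y, a_max = NULL, folds = 5, seed = 1L) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (is.null(a_max)) a_max <- min(ncol(P), 10, n - 2)
  a_max <- max(1, a_max)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  press <- numeric(a_max)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    for (a in seq_len(a_max)) {
      fit <- try(fit_pls(P[tr, , drop = FALSE], y[tr], a = a), silent = TRUE)
      if (inherits(fit, "try-error")) {
        press[a] <- Inf
        next
      }
      pred <- predict_pls(fit, P[!tr, , drop = FALSE])
      press[a] <- press[a] + sum((y[!tr] - pred)^2)
    }
  }
  rmsep <- sqrt(press / n)
  which(rmsep <= min(rmsep) * 1.01)[1]
}

#' Variable importance in projection
#'
#' \deqn{VIP_j = \sqrt{ s \sum_a SS_a (w_{ja}/\|w_a\|)^2 / \sum_a SS_a }}
#' where \eqn{SS_a} is the response variance captured by component a. The
#' mean squared VIP equals 1 by construction, so 1 is the conventional
#' relevance threshold.
#'
#' @param pls A [fit_pls()] model.
#' @return Named numeric vector of length s.
#' @export
vip_scores <- function(pls) {
  W <- pls$x_weights                      # columns already unit norm
  s <- nrow(W)
  frac <- pls$ss_comp / sum(pls$ss_comp)
  vip <- sqrt(s * as.numeric(W^2 %*% frac))
  setNames(vip, names(pls$coefficients))
}

#' Rank parameters by the magnitude of their regression coefficients
#'
#' @param pls A [fit_pls()] model.
#' @return Data frame with `param`, `coefficient`, `sign`, ordered by
#'   decreasing `|coefficient|`.
#' @export
coefficient_ranking <- function(pls) {
  beta <- pls$coefficients
  ord <- order(-abs(beta))
  data.frame(param = names(beta)[ord],
             coefficient = as.numeric(beta[ord]),
             sign = ifelse(beta[ord] >= 0, "+", "-"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Refit the regression separately within each fate class
#'
#' When the pooled fit has to bridge well-separated state clouds, per-class
#' fits are tighter; they are the basis for per-fate importance rankings.
#'
#' @param P Predictor matrix.
#' @param y Response.
#' @param labels Class label per row.
#' @param a Components per fit (`NULL` = per-class cross-validation).
#' @return Named list of `pls_model`s, one per class.
#' @export
per_class_refit <- function(P, y, labels, a = NULL) {
  P <- as.matrix(P)
  out <- list()
  for (cl in sort(unique(labels))) {
    idx <- labels == cl
    need <- if (is.null(a)) 3 else a + 2
    if (sum(idx) < need)
      stop("class '", cl, "' has only ", sum(idx), " rows; too few to refit")
    out[[as.character(cl)]] <-
      fit_pls(P[idx, , drop = FALSE], y[idx], a = a)
  }
  out
}

#' Build a confidence-interval classification rule
#'
#' For each class and confidence level c, the decision interval covers the
#' central c mass of that class's training fitted values: Gaussian intervals
#' (mean +/- z sd, the default) or empirical quantile ranges. At
#' classification time only the facing (inner) edges separate classes: the
#' lowest class claims everything below its upper edge and the highest class
#' everything above its lower edge, mirroring threshold rules such as "fitted
#' response below the epithelial edge means epithelial". A fitted value in
#' the uncovered gap between intervals is unclassifiable (scored false); one
#' claimed by several overlapping intervals falls back to the class with the
#' nearest training median.
#'
#' Gaussian intervals reach through the low-density region between well-
#' separated classes, so on cleanly bimodal data accuracy saturates and
#' barely changes with the confidence level; quantile intervals stop at the
#' data's inner edge and leave an unclassifiable gap there.
#'
#' @param pls A [fit_pls()] model (fitted on the training rows).
#' @param labels Training class label per row.
#' @param ci_levels Confidence levels, e.g. `c(0.90, 0.95, 0.99)`.
#' @param interval_type `"gaussian"` (mean +/- z sd) or `"quantile"`
#'   (central empirical quantile range).
#' @return An object of class `fate_rule`: per-level interval table,
#'   class medians, the `pls` model.
#' @export
build_rule <- function(pls, labels, ci_levels = c(0.90, 0.95, 0.99),
                       interval_type = c("gaussian", "quantile")) {
  interval_type <- match.arg(interval_type)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to build a rule")
  fitted <- pls$fitted
  medians <- vapply(classes, function(cl) median(fitted[labels == cl]), 0)
  if (anyDuplicated(medians))
    stop("classes have identical fitted-value medians; nothing separates them")
  ord <- order(medians)
  classes <- classes[ord]
  medians <- medians[ord]
  intervals <- lapply(ci_levels, function(c) {
    t(vapply(classes, function(cl) {
      v <- fitted[labels == cl]
      if (interval_type == "gaussian") {
        mean(v) + c(-1, 1) * qnorm((1 + c) / 2) * sd(v)
      } else {
        quantile(v, c((1 - c) / 2, (1 + c) / 2), names = FALSE)
      }
    }, numeric(2)))
  })
  names(intervals) <- as.character(ci_levels)
  structure(list(pls = pls, classes = classes, medians = medians,
                 ci_levels = ci_levels, intervals = intervals,
                 interval_type = interval_type),
            class = "fate_rule")
}

#' @export
print.fate_rule <- function(x, ...) {
  cat("<fate_rule> classes: ", paste(x$classes, collapse = " < "),
      " (by fitted median); CI levels: ",
      paste(x$ci_levels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify parameter sets with a confidence-interval rule
#'
#' @param rule A [build_rule()] result.
#' @param P_new Parameter matrix on the training predictor scale.
#' @param ci_level One of the rule's confidence levels.
#' @return Data frame with `fitted`, `class` (NA when unclassifiable) and
#'   `status` (`"unique"`, `"ambiguous"` resolved by nearest median, or
#'   `"unclassified"`).
#' @export
classify_params <- function(rule, P_new, ci_level = rule$ci_levels[1]) {
  key <- as.character(ci_level)
  if (!key %in% names(rule$intervals))
    stop("rule has no intervals at level ", ci_level)
  iv <- rule$intervals[[key]]
  k <- length(rule$classes)
  lo <- iv[, 1]; hi <- iv[, 2]
  lo[1] <- -Inf                      # outermost classes claim the tails
  hi[k] <- Inf
  fitted <- predict_pls(rule$pls, P_new)
  cls <- character(length(fitted))
  status <- character(length(fitted))
  for (i in seq_along(fitted)) {
    inside <- which(fitted[i] >= lo & fitted[i] <= hi)
    if (length(inside) == 1) {
      cls[i] <- as.character(rule$classes[inside])
      status[i] <- "unique"
    } else if (length(inside) > 1) {
      nearest <- inside[which.min(abs(fitted[i] - rule$medians[inside]))]
      cls[i] <- as.character(rule$classes[nearest])
      status[i] <- "ambiguous"
    } else {
      cls[i] <- NA_character_
      status[i] <- "unclassified"
    }
  }
  data.frame(fitted = fitted, class = cls, status = status,
             stringsAsFactors = FALSE)
}

#' Evaluate a classification rule on held-out data
#'
#' A test row is counted true when its assigned class matches the fate the
#' ODE model actually reached, false otherwise; unclassifiable rows count as
#' false. Accuracy is reported per class and confidence level, the layout of
#' the classification-accuracy tables.
#'
#' @param rule A [build_rule()] result.
#' @param P_test Held-out parameter matrix (training predictor scale).
#' @param labels_test True class per test row.
#' @return An object of class `accuracy_report`: data frame with columns
#'   `ci_level`, `class`, `n_test`, `n_true`, `n_false`, `accuracy`.
#' @export
evaluate_rule <- function(rule, P_test, labels_test) {
  rows <- list()
  for (c in rule$ci_levels) {
    pred <- classify_params(rule, P_test, ci_level = c)
    for (cl in rule$classes) {
      idx <- labels_test == cl
      n_test <- sum(idx)
      if (n_test == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          ci_level = c, class = as.character(cl), n_test = 0L,
          n_true = NA_integer_, n_false = NA_integer_, accuracy = NA_real_)
        next
      }
      n_true <- sum(idx & !is.na(pred$class) & pred$class == as.character(cl))
      rows[[length(rows) + 1]] <- data.frame(
        ci_level = c, class = as.character(cl), n_test = n_test,
        n_true = n_true, n_false = n_test - n_true,
        accuracy = n_true / n_test)
    }
  }
  structure(do.call(rbind, rows), class = c("accuracy_report", "data.frame"))
}

#' Stratified train/test split
#'
#' @param labels Class label per row.
#' @param train_frac Fraction assigned to training (per class).
#' @param seed Split seed.
#' @return Logical vector, `TRUE` for training rows.
#' @export
train_test_split <- function(labels, train_frac = 0.70, seed = 1L) {
  train <- logical(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(train_frac * length(idx))
      train[sample(idx, n_tr)] <- TRUE
    }
  })
  train
}

#' Reshape an accuracy report into the tabulated wide layout
#'
#' One row per confidence level; per class a True / False / Accuracy column
#' triplet, the layout of the printed classification-accuracy tables.
#'
#' @param report An [evaluate_rule()] result.
#' @return A wide data frame.
#' @export
accuracy_table <- function(report) {
  df <- as.data.frame(report)
  levels <- unique(df$ci_level)
  classes <- unique(df$class)
  out <- data.frame(ci_level = levels)
  for (cl in classes) {
    sub <- df[df$class == cl, ]
    sub <- sub[match(levels, sub$ci_level), ]
    out[[paste0("true_", cl)]] <- sub$n_true
    out[[paste0("false_", cl)]] <- sub$n_false
    out[[paste0("accuracy_", cl)]] <- sub$accuracy
  }
  out
}
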
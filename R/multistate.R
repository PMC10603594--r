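#' Learn a critical value separating two fate classes on PC1
#'
#' The monostable states of the two classes occupy opposite ends of the PC1
#' axis; the critical value is the midpoint between the facing empirical
#' class boundaries (the upper tail quantile of the lower class and the
#' lower tail quantile of the upper class). Which side maps to which class
#' is learned from the data, never hard-coded, because the PCA sign
#' convention fixes the axis orientation only up to the data at hand.
#'
#' @param pc1 PC1 scores of monostable states.
#' @param labels Two-class label per score.
#' @param tail Tail probability defining the facing boundaries (default
#'   0.005, i.e. half-percent tails).
#' @param overlap_tol If the facing boundaries overlap by more than this
#'   fraction of the between-median distance, the rule is flagged
#'   low-confidence with a warning.
#' @return An object of class `critical_value_rule`: `vc`, `class_below`,
#'   `class_above`, `low_confidence`.
#' @export
fit_critical_value <- function(pc1, labels, tail = 0.005, overlap_tol = 0.25) {
  classes <- sort(unique(labels))
  if (length(classes) != 2)
    stop("critical-value rule needs exactly 2 classes, got ", length(classes))
  med <- vapply(classes, function(cl) median(pc1[labels == cl]), 0)
  lo_class <- classes[which.min(med)]
  hi_class <- classes[which.max(med)]
  upper_of_lo <- quantile(pc1[labels == lo_class], 1 - tail, names = FALSE)
  lower_of_hi <- quantile(pc1[labels == hi_class], tail, names = FALSE)
  vc <- (upper_of_lo + lower_of_hi) / 2
  gap <- lower_of_hi - upper_of_lo
  low_confidence <- gap < -overlap_tol * abs(diff(med))
  if (low_confidence)
    warning("classes overlap substantially along PC1; ",
            "critical-value rule flagged low-confidence")
  structure(list(vc = vc, class_below = as.character(lo_class),
                 class_above = as.character(hi_class),
                 low_confidence = low_confidence),
            class = "critical_value_rule")
}

#' @export
print.critical_value_rule <- function(x, ...) {
  cat("<critical_value_rule> Vc = ", signif(x$vc, 5), "; below -> ",
      x$class_below, ", above -> ", x$class_above,
      if (x$low_confidence) "  [low confidence]", "\n", sep = "")
  invisible(x)
}

#' Fit per-class confidence ellipses on the PC1-PC2 plane
#'
#' Each class is summarized by its mean and covariance; a point belongs to a
#' class's ellipse when its squared Mahalanobis distance is at most the
#' chi-square quantile with 2 degrees of freedom at the chosen level.
#'
#' @param scores2d q x 2 score matrix (PC1, PC2).
#' @param labels Class per row (three classes for E / hybrid / M systems).
#' @param level Coverage level of the ellipses.
#' @return An object of class `ellipse_rule`: per class `center`, `cov`,
#'   plus `radius2` and `level`.
#' @export
fit_ellipses <- function(scores2d, labels, level = 0.95) {
  scores2d <- as.matrix(scores2d)
  stopifnot(ncol(scores2d) == 2)
  classes <- sort(unique(labels))
  per_class <- lapply(classes, function(cl) {
    pts <- scores2d[labels == cl, , drop = FALSE]
    if (nrow(pts) < 3)
      stop("class '", cl, "' has fewer than 3 points; cannot fit an ellipse")
    S <- cov(pts)
    if (rcond(S) < 1e-12) {
      eps <- 1e-8 * mean(diag(S))
      message("singular covariance for class '", cl,
              "'; ridge-regularized with epsilon ", signif(eps, 3))
      S <- S + diag(eps, 2)
    }
    list(center = colMeans(pts), cov = S)
  })
  names(per_class) <- as.character(classes)
  structure(list(classes = as.character(classes), per_class = per_class,
                 level = level, radius2 = qchisq(level, df = 2)),
            class = "ellipse_rule")
}

#' @export
print.ellipse_rule <- function(x, ...) {
  cat("<ellipse_rule> classes: ", paste(x$classes, collapse = ", "),
      "; level ", x$level, " (radius^2 = ", round(x$radius2, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Classify multistable states with a learned rule
#'
#' States must be projected with the same PCA model used to build the rule.
#' Under a critical-value rule the PC1 side decides the class; under an
#' ellipse rule a state takes the class of the ellipse containing it (the
#' nearest by Mahalanobis distance when ellipses overlap) and is
#' `"unclassified"` when it falls in no ellipse.
#'
#' @param rule A [fit_critical_value()] or [fit_ellipses()] result.
#' @param scores Projected states: PC1 vector (or 1+ column matrix) for a
#'   critical-value rule, a 2-column matrix for an ellipse rule.
#' @return Character vector of class labels.
#' @export
classify_multistable <- function(rule, scores) {
  if (inherits(rule, "critical_value_rule")) {
    pc1 <- if (is.null(dim(scores))) scores else scores[, 1]
    return(ifelse(pc1 > rule$vc, rule$class_above, rule$class_below))
  }
  if (inherits(rule, "ellipse_rule")) {
    scores <- as.matrix(scores)
    stopifnot(ncol(scores) == 2)
    d2 <- vapply(rule$per_class, function(e)
      mahalanobis(scores, e$center, e$cov), numeric(nrow(scores)))
    d2 <- matrix(d2, nrow = nrow(scores))
    out <- character(nrow(scores))
    for (i in seq_len(nrow(scores))) {
      inside <- which(d2[i, ] <= rule$radius2)
      out[i] <- if (length(inside) == 0) "unclassified"
                else rule$classes[inside[which.min(d2[i, inside])]]
    }
    return(out)
  }
  stop("rule must be a critical_value_rule or an ellipse_rule")
}

#' Membership test for an ellipse rule
#'
#' @param rule A [fit_ellipses()] result.
#' @param scores 2-column score matrix.
#' @param class Class name.
#' @return Logical vector: inside that class's ellipse.
#' @export
in_ellipse <- function(rule, scores, class) {
  e <- rule$per_class[[as.character(class)]]
  if (is.null(e)) stop("no ellipse for class '", class, "'")
  mahalanobis(as.matrix(scores), e$center, e$cov) <= rule$radius2
}

#' Predict mono- versus multistability from parameters
#'
#' Fits a radial-basis kernel support vector machine on normalized parameter
#' vectors labelled mono/multi, with the cost parameter grid-searched by
#' 5-fold cross-validation.
#'
#' @param P_train Normalized parameter matrix (training rows).
#' @param stability_labels Factor or character: `"mono"` / `"multi"` per row.
#' @param cost_grid Candidate soft-margin costs.
#' @param seed Cross-validation seed.
#' @return An object of class `mono_multi_svm` wrapping the fitted
#'   `kernlab::ksvm` model.
#' @export
fit_mono_multi_svm <- function(P_train, stability_labels,
                               cost_grid = c(1, 10, 100), seed = 1L) {
  y <- factor(stability_labels)
  if (nlevels(y) < 2) stop("both stability labels must be present")
  P_train <- as.matrix(P_train)
  cv_err <- vapply(cost_grid, function(C) {
    fit <- with_seed(seed, kernlab::ksvm(P_train, y, kernel = "rbfdot",
                                         C = C, cross = 5))
    kernlab::cross(fit)
  }, 0)
  best_C <- cost_grid[which.min(cv_err)]
  fit <- with_seed(seed, kernlab::ksvm(P_train, y, kernel = "rbfdot",
                                       C = best_C))
  structure(list(fit = fit, cost = best_C, cv_error = min(cv_err),
                 levels = levels(y)),
            class = "mono_multi_svm")
}

#' @export
print.mono_multi_svm <- function(x, ...) {
  cat("<mono_multi_svm> RBF kernel, C = ", x$cost, ", CV error = ",
      round(x$cv_error, 4), "\n", sep = "")
  invisible(x)
}

#' Predict stability class for new parameter sets
#' @param svm A [fit_mono_multi_svm()] result.
#' @param P_new Normalized parameter matrix.
#' @return Factor of predicted labels.
#' @export
predict_mono_multi <- function(svm, P_new) {
  kernlab::predict(svm$fit, as.matrix(P_new))
}
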
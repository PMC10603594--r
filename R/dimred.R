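#' Principal component analysis of steady-state matrices
#'
#' Centered (optionally z-scored) PCA with a fixed sign convention: each
#' component is flipped, if necessary, so that its largest-magnitude loading
#' is positive. This makes scores reproducible across runs and platforms;
#' note that decision thresholds learned on PC1 (critical values, class
#' edges) are orientation-dependent quantities and are always learned in
#' this convention rather than hard-coded.
#'
#' @param X q x m data matrix.
#' @param r Number of components to keep (1 <= r < q).
#' @param standardize Z-score columns before the decomposition. Recommended
#'   when variables span different magnitudes (e.g. microRNA versus protein
#'   levels).
#' @return An object of class `pca_model`: `mean`, `scale` (1s when
#'   unscaled), `loadings` (m x r orthonormal), `explained_var_ratio`,
#'   `scores` (training scores), `sign_flipped` (logical per component).
#' @export
fit_pca <- function(X, r = 2, standardize = FALSE) {
  X <- as.matrix(X)
  stopifnot(r >= 1, nrow(X) > r)
  sds <- apply(X, 2, sd)
  if (all(sds < .Machine$double.eps))
    stop("constant matrix: no variance to decompose")
  if (standardize && any(sds < .Machine$double.eps))
    stop("cannot standardize: column(s) with zero variance")
  pr <- prcomp(X, center = TRUE, scale. = standardize)
  r <- min(r, ncol(pr$rotation))
  loadings <- pr$rotation[, seq_len(r), drop = FALSE]
  flipped <- logical(r)
  for (j in seq_len(r)) {
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      flipped[j] <- TRUE
    }
  }
  evr <- pr$sdev^2 / sum(pr$sdev^2)
  model <- structure(
    list(mean = pr$center,
         scale = if (standardize) pr$scale else rep(1, ncol(X)),
         loadings = loadings,
         explained_var_ratio = evr[seq_len(r)],
         sign_flipped = flipped),
    class = "pca_model")
  model$scores <- project(model, X)
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> ", ncol(x$loadings), " component(s); explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_var_ratio), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Project new states into a fitted PCA space
#'
#' @param model A [fit_pca()] result.
#' @param X_new Matrix (or vector) with the same columns as the training data.
#' @return Score matrix with one column per retained component.
#' @export
project <- function(model, X_new) {
  if (is.null(dim(X_new))) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$mean))
    stop("X_new has ", ncol(X_new), " columns; the PCA was fitted on ",
         length(model$mean))
  scores <- sweep(sweep(X_new, 2, model$mean), 2, model$scale, "/") %*%
    model$loadings
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  scores
}

#' Reconstruct states from PCA scores
#'
#' @param model A [fit_pca()] result.
#' @param scores Score matrix.
#' @return Matrix on the original data scale.
#' @export
backproject <- function(model, scores) {
  sweep(sweep(as.matrix(scores) %*% t(model$loadings), 2, model$scale, "*"),
        2, model$mean, "+")
}

#' Serialize a PCA model to JSON
#' @param model A `pca_model`.
#' @param path Optional file path.
#' @return JSON string (invisibly when written).
#' @export
pca_to_json <- function(model, path = NULL) {
  obj <- list(mean = model$mean, scale = model$scale,
              loadings = apply(model$loadings, 2, identity, simplify = FALSE),
              explained_var_ratio = model$explained_var_ratio)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
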
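#' Cluster steady states into fate classes
#'
#' Average-linkage hierarchical clustering with the Euclidean metric, with
#' the tree cut to exactly `k` clusters. Cluster labels are renumbered by
#' descending cluster size so that label 1 is always the largest fate class,
#' which makes labellings comparable across runs. Clustering operates on raw
#' steady states by default; `standardize` switches to per-column z-scores
#' when the state variables span very different magnitudes.
#'
#' @param X_mono q' x m matrix of monostable steady states.
#' @param k Number of fate classes (>= 2).
#' @param standardize Z-score columns before computing distances.
#' @param method Linkage passed to [stats::hclust()]; the fate-clustering
#'   default is `"average"`.
#' @return An object of class `fate_labeling`: `labels` (integer in 1..k),
#'   `k`, `sizes`, `tree` (the `hclust` merge structure), `centers`
#'   (k x m matrix of cluster means on the original scale).
#' @export
cluster_fates <- function(X_mono, k = 2, standardize = FALSE,
                          method = "average") {
  X_mono <- as.matrix(X_mono)
  if (k > nrow(X_mono)) stop("k = ", k, " exceeds the ", nrow(X_mono),
                             " available states")
  if (k < 2) stop("k must be at least 2")
  Xd <- if (standardize) scale(X_mono) else X_mono
  tree <- hclust(dist(Xd, method = "euclidean"), method = method)
  raw <- cutree(tree, k = k)
  # renumber by descending size; ties broken by first appearance
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- integer(k)
  relabel[as.integer(names(sizes))[ord]] <- seq_len(k)
  labels <- relabel[raw]
  centers <- do.call(rbind, lapply(seq_len(k), function(c)
    colMeans(X_mono[labels == c, , drop = FALSE])))
  structure(list(labels = labels, k = k,
                 sizes = as.integer(table(labels)), tree = tree,
                 centers = centers),
            class = "fate_labeling")
}

#' @export
print.fate_labeling <- function(x, ...) {
  cat("<fate_labeling> k = ", x$k, "; sizes: ",
      paste(x$sizes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Name fate classes from a marker variable
#'
#' Convenience for attaching biological names: classes are ordered by their
#' mean value of `marker` and given `names` in that order (e.g. E-cadherin
#' high first for epithelial-vs-mesenchymal labelling).
#'
#' @param labeling A [cluster_fates()] result.
#' @param X The matrix the labeling was fit on.
#' @param marker Column name or index to order classes by.
#' @param names Character vector of length `k`, low-to-high marker order.
#' @param decreasing Order classes by decreasing marker mean instead.
#' @return The labeling with a `class_names` field (named by class label).
#' @export
name_fates_by_marker <- function(labeling, X, marker, names,
                                 decreasing = FALSE) {
  stopifnot(length(names) == labeling$k)
  means <- vapply(seq_len(labeling$k), function(c)
    mean(X[labeling$labels == c, marker]), 0)
  ord <- order(means, decreasing = decreasing)
  cn <- character(labeling$k)
  cn[ord] <- names
  labeling$class_names <- cn
  labeling
}

#' Remove hybrid-state parameter rows from a dataset
#'
#' For three-class systems (e.g. epithelial / hybrid / mesenchymal), removes
#' every state produced by a parameter row that has at least one hybrid
#' member -- including that row's non-hybrid states -- leaving only rows
#' whose full state set is free of the hybrid class. Hybrid identification
#' defaults to the middle cluster of a `k = 3` cut over all states (the class
#' whose center is intermediate along the dominant axis); an explicit
#' per-state logical can override it.
#'
#' @param ds A `fate_dataset`.
#' @param is_hybrid Optional logical vector over the rows of `ds$X` marking
#'   hybrid states. When missing, a k = 3 Ward clustering of all states
#'   (standardized) is used and the middle class along PC1 is taken as
#'   hybrid.
#' @return The filtered `fate_dataset` (a row-subset view).
#' @export
filter_hybrid_for_em <- function(ds, is_hybrid = NULL) {
  if (is.null(is_hybrid)) {
    # Ward linkage here: average linkage chains the epithelial and hybrid
    # clouds and strands singletons on this geometry
    lab <- cluster_fates(ds$X, k = 3, standardize = TRUE, method = "ward.D2")
    pc1 <- fit_pca(ds$X, r = 1, standardize = TRUE)
    center_scores <- project(pc1, lab$centers)[, 1]
    hybrid_class <- which(rank(center_scores) == 2)  # intermediate along PC1
    is_hybrid <- lab$labels == hybrid_class
  }
  stopifnot(length(is_hybrid) == nrow(ds$X))
  bad_rows <- unique(ds$row_to_param[is_hybrid])
  keep_rows <- setdiff(unique(ds$row_to_param), bad_rows)
  subset_dataset(ds, keep_rows)
}

#' Export a linkage tree as a flat merge table
#'
#' One row per merge: the two children (negative = original observation,
#' positive = earlier merge, the `hclust` convention) and the merge height.
#'
#' @param labeling A [cluster_fates()] result.
#' @param path Optional file path for a TSV; when `NULL` the data frame is
#'   returned.
#' @return Data frame with columns `child1`, `child2`, `height`.
#' @export
export_linkage <- function(labeling, path = NULL) {
  tree <- labeling$tree
  df <- data.frame(child1 = tree$merge[, 1], child2 = tree$merge[, 2],
                   height = tree$height)
  if (is.null(path)) return(df)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
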
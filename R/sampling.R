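#' Draw a random parameter sample
#'
#' Each parameter is drawn i.i.d. from the uniform distribution on its
#' perturbation interval. `fixed` pins named parameters to constants (their
#' interval is recorded as degenerate), which is how experiments that perturb
#' only a subset of parameters keep the rest at basal values.
#'
#' @param model A [fate_model()], or an s x 2 matrix of intervals with row
#'   names taken as parameter names.
#' @param n Number of parameter sets to draw.
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @param fixed Optional named numeric vector of parameters to hold constant.
#' @return An object of class `parameter_sample`: list with `P` (n x s
#'   matrix), `intervals`, `param_names`, `varying` (logical), `seed`.
#' @export
sample_parameters <- function(model, n, seed = 1L, fixed = NULL) {
  stopifnot(n >= 1)
  if (inherits(model, "fate_model")) {
    intervals <- model$perturb_intervals
    pnames <- model$param_names
  } else {
    intervals <- as.matrix(model)
    pnames <- rownames(intervals)
    if (is.null(pnames)) stop("interval matrix needs parameter row names")
  }
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), pnames)
    if (length(bad))
      stop("unknown parameter name(s) in fixed: ", paste(bad, collapse = ", "))
    intervals[names(fixed), 1] <- fixed
    intervals[names(fixed), 2] <- fixed
  }
  s <- length(pnames)
  varying <- intervals[, 1] < intervals[, 2]
  P <- with_seed(seed, {
    draws <- matrix(runif(n * s), n, s)
    sweep(sweep(draws, 2, intervals[, 2] - intervals[, 1], "*"),
          2, intervals[, 1], "+")
  })
  colnames(P) <- pnames
  structure(list(P = P, intervals = intervals, param_names = pnames,
                 varying = varying, seed = as.integer(seed)),
            class = "parameter_sample")
}

#' @export
print.parameter_sample <- function(x, ...) {
  cat("<parameter_sample> ", nrow(x$P), " draws x ", ncol(x$P),
      " parameters (", sum(x$varying), " varying), seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Build the paired parameter / steady-state dataset
#'
#' Runs [find_steady_states()] for every parameter row and assembles the
#' stacked steady-state matrix X (q x m, q >= number of solved rows because
#' multistable rows contribute several states), the row-to-parameter index,
#' per-row state counts and mono/multi masks. Per-row solver seeds are
#' derived deterministically from the sample seed, so rows are independent
#' and the dataset is reproducible.
#'
#' Parameter rows whose solve fails are dropped with a message rather than
#' aborting the sweep; their count is recorded in `n_failed`.
#'
#' @param model A [fate_model()].
#' @param sample A [sample_parameters()] result.
#' @param control Solver settings from [ss_control()].
#' @param progress_every Log a progress line every this many rows (0 = quiet).
#' @return An object of class `fate_dataset`: list with `X`, `row_to_param`,
#'   `n_states_per_param`, `mono_mask`, `multi_mask`, `fate_labels`
#'   (initialised to `NA`), `sample`, `model_name`, `n_failed`.
#' @export
build_dataset <- function(model, sample, control = ss_control(),
                          progress_every = 0) {
  stopifnot(identical(colnames(sample$P), model$param_names))
  n <- nrow(sample$P)
  states <- vector("list", n)
  counts <- integer(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    res <- try(find_steady_states(model, sample$P[i, ],
                                  seed = derive_seed(sample$seed, i),
                                  control = control, param_index = i),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      counts[i] <- 0L
      next
    }
    states[[i]] <- res$states
    counts[i] <- res$n_states
    ok[i] <- TRUE
    if (progress_every > 0 && i %% progress_every == 0)
      message("solved ", i, "/", n, " parameter rows")
  }
  n_failed <- sum(!ok)
  if (n_failed > 0)
    message(n_failed, " parameter row(s) produced no attractor and were dropped")
  X <- do.call(rbind, states[ok])
  row_to_param <- rep(which(ok), counts[ok])
  structure(
    list(X = X, row_to_param = row_to_param, n_states_per_param = counts,
         mono_mask = counts == 1L, multi_mask = counts >= 2L,
         fate_labels = rep(NA_integer_, nrow(X)),
         sample = sample, model_name = model$name, n_failed = n_failed),
    class = "fate_dataset")
}

#' @export
print.fate_dataset <- function(x, ...) {
  n_solved <- sum(x$n_states_per_param > 0)
  cat("<fate_dataset> model '", x$model_name, "': ", nrow(x$X),
      " states from ", n_solved, " parameter sets (",
      sum(x$mono_mask), " mono, ", sum(x$multi_mask), " multi)\n", sep = "")
  invisible(x)
}

# per-row solver seed derived from the master seed; kept inside 32-bit range
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807) %% 2147483647)
}

#' Split a dataset into monostable and multistable views
#'
#' Partitions the parameter rows by their state count. Both views keep the
#' original `row_to_param` indices so the union reconstitutes the dataset.
#'
#' @param ds A [build_dataset()] result.
#' @return List with elements `mono` and `multi`, each a `fate_dataset` view.
#' @export
split_mono_multi <- function(ds) {
  make_view <- function(mask_rows) {
    keep <- ds$row_to_param %in% mask_rows
    out <- ds
    out$X <- ds$X[keep, , drop = FALSE]
    out$row_to_param <- ds$row_to_param[keep]
    out$fate_labels <- ds$fate_labels[keep]
    out
  }
  list(mono = make_view(which(ds$mono_mask)),
       multi = make_view(which(ds$multi_mask)))
}

#' Restrict a dataset to a subset of parameter rows
#'
#' @param ds A `fate_dataset`.
#' @param param_rows Integer indices of parameter rows to keep.
#' @return A `fate_dataset` view.
#' @export
subset_dataset <- function(ds, param_rows) {
  keep <- ds$row_to_param %in% param_rows
  ds$X <- ds$X[keep, , drop = FALSE]
  ds$row_to_param <- ds$row_to_param[keep]
  ds$fate_labels <- ds$fate_labels[keep]
  ds
}
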
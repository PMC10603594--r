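#' Solver settings for steady-state enumeration
#'
#' Defaults were chosen so that downstream summary statistics (for example the
#' toggle-switch bistable fraction) are insensitive to doubling any of them.
#'
#' @param n_starts Number of random initial conditions per parameter set.
#' @param t_chunk Integration horizon per convergence check, in model time.
#' @param t_max Hard integration horizon; non-converged trajectories are
#'   dropped rather than erroring so that slow or oscillatory dynamics do not
#'   abort a long sweep.
#' @param conv_tol Convergence tolerance on the windowed state change and on
#'   the residual derivative norm during integration.
#' @param root_tol Max-norm tolerance on the right-hand side at an accepted
#'   root after Newton polishing.
#' @param merge_tol Relative per-component tolerance under which two roots
#'   are considered the same state.
#' @param stab_margin A root is accepted as stable only if the largest real
#'   part of its Jacobian eigenvalues is below `-stab_margin`.
#' @param newton_max Maximum damped-Newton iterations per polish.
#' @return A list of solver settings.
#' @export
ss_control <- function(n_starts = 20, t_chunk = 150, t_max = 3000,
                       conv_tol = 1e-8, root_tol = 1e-9, merge_tol = 1e-3,
                       stab_margin = 1e-8, newton_max = 50) {
  list(n_starts = n_starts, t_chunk = t_chunk, t_max = t_max,
       conv_tol = conv_tol, root_tol = root_tol, merge_tol = merge_tol,
       stab_margin = stab_margin, newton_max = newton_max)
}

#' Find all stable steady states of a model at one parameter set
#'
#' Integrates from `n_starts` random nonnegative initial conditions until the
#' trajectory settles, polishes each endpoint with a damped Newton root
#' solve, keeps only roots that are asymptotically stable (all Jacobian
#' eigenvalues with negative real part), merges duplicates, and returns the
#' distinct states sorted by their first component. Deterministic given
#' `(params, n_starts, seed)`.
#'
#' @param model A [fate_model()].
#' @param params Numeric parameter vector in model order.
#' @param seed Integer seed for the random initial conditions.
#' @param control Solver settings from [ss_control()].
#' @param param_index Optional integer tag linking the result to a parameter
#'   row in a larger sample.
#' @return An object of class `steady_state_set` with elements `states`
#'   (n_states x m matrix), `n_states`, `is_multistable`, `param_index`.
#' @export
find_steady_states <- function(model, params, seed = 1L,
                               control = ss_control(), param_index = NA_integer_) {
  stopifnot(control$n_starts >= 1)
  params <- as.numeric(params)
  m <- length(model$state_names)
  ics <- with_seed(seed, {
    matrix(runif(control$n_starts * m), control$n_starts, m) %*%
      diag(model$ic_range, m)
  })
  f <- function(y) evaluate_rhs(model, y, params)
  jac <- function(y) evaluate_jacobian(model, y, params)

  found <- list()
  for (i in seq_len(control$n_starts)) {
    y_end <- integrate_to_rest(model, ics[i, ], params, control)
    if (is.null(y_end)) next
    root <- newton_polish(f, jac, y_end, control)
    if (is.null(root)) next
    if (any(root < -1e-6 * max(1, max(abs(root))))) next  # left the nonnegative cone
    if (!is_stable(jac(root), control$stab_margin)) next
    found <- c(found, list(pmax(root, 0)))
  }
  if (length(found) == 0)
    stop("no attractor found for parameter row ", param_index,
         " after ", control$n_starts, " starts; increase n_starts or t_max")
  states <- merge_duplicate_states(do.call(rbind, found), control$merge_tol)
  states <- states[order(states[, 1]), , drop = FALSE]
  colnames(states) <- model$state_names
  structure(
    list(states = states, n_states = nrow(states),
         is_multistable = nrow(states) >= 2, param_index = param_index),
    class = "steady_state_set")
}

#' @export
print.steady_state_set <- function(x, ...) {
  cat("<steady_state_set> ", x$n_states, " stable state(s)",
      if (x$is_multistable) " [multistable]", "\n", sep = "")
  print(round(x$states, 4))
  invisible(x)
}

#' Stability of a steady state
#'
#' @inheritParams find_steady_states
#' @param state A steady state (residual below the root tolerance).
#' @param stab_margin Margin on the eigenvalue real parts.
#' @return `TRUE` iff the largest real part of the Jacobian eigenvalues is
#'   below `-stab_margin`.
#' @export
label_stability <- function(model, params, state, stab_margin = 1e-8) {
  is_stable(evaluate_jacobian(model, state, params), stab_margin)
}

is_stable <- function(J, stab_margin) {
  ev <- eigen(J, only.values = TRUE)$values
  max(Re(ev)) < -stab_margin
}

# integrate until the state settles (windowed change and residual both small);
# returns NULL when the trajectory has not settled by t_max or went non-finite
integrate_to_rest <- function(model, y0, params, control) {
  y <- as.numeric(y0)
  t_done <- 0
  while (t_done < control$t_max) {
    y_new <- integrate_chunk(model, y, params, control$t_chunk)
    if (is.null(y_new) || any(!is.finite(y_new))) return(NULL)
    step <- max(abs(y_new - y)) / max(1, max(abs(y_new)))
    y <- y_new
    t_done <- t_done + control$t_chunk
    if (step < control$conv_tol) return(y)
    resid <- max(abs(evaluate_rhs(model, y, params)))
    if (resid < 1e-6) return(y)
  }
  # hand the endpoint to Newton anyway if it is nearly at rest
  if (max(abs(evaluate_rhs(model, y, params))) < 1e-3) y else NULL
}

integrate_chunk <- function(model, y, params, t_chunk) {
  times <- c(0, t_chunk)
  out <- if (!is.null(model$dll)) {
    try(deSolve::lsoda(y, times, func = model$dll$func, parms = params,
                       dllname = model$dll$dllname,
                       initfunc = model$dll$initfunc,
                       rtol = 1e-8, atol = 1e-10), silent = TRUE)
  } else {
    rhs <- model$rhs
    try(deSolve::lsoda(y, times, function(t, y, p) list(rhs(y, p)),
                       parms = params, rtol = 1e-8, atol = 1e-10),
        silent = TRUE)
  }
  if (inherits(out, "try-error") || nrow(out) < 2) return(NULL)
  as.numeric(out[nrow(out), -1])
}

# damped Newton; returns NULL when it fails to reach root_tol
newton_polish <- function(f, jac, y0, control) {
  y <- y0
  fy <- f(y)
  for (it in seq_len(control$newton_max)) {
    nf <- max(abs(fy))
    if (!is.finite(nf)) return(NULL)
    if (nf < control$root_tol) return(y)
    J <- jac(y)
    delta <- try(solve(J, -fy), silent = TRUE)
    if (inherits(delta, "try-error")) return(NULL)
    lambda <- 1
    repeat {
      y_new <- y + lambda * delta
      f_new <- f(y_new)
      if (all(is.finite(f_new)) && max(abs(f_new)) < nf) break
      lambda <- lambda / 2
      if (lambda < 1e-4) return(NULL)
    }
    y <- y_new
    fy <- f_new
  }
  if (max(abs(fy)) < control$root_tol) y else NULL
}

# relative per-component merge against the typical scale of each variable
merge_duplicate_states <- function(states, merge_tol) {
  scale <- pmax(apply(abs(states), 2, max), 1e-3)
  kept <- states[1, , drop = FALSE]
  for (i in seq_len(nrow(states))[-1]) {
    dup <- FALSE
    for (j in seq_len(nrow(kept))) {
      if (max(abs(states[i, ] - kept[j, ]) / scale) < merge_tol) {
        dup <- TRUE
        break
      }
    }
    if (!dup) kept <- rbind(kept, states[i, ])
  }
  kept
}

# run code with a local RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
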
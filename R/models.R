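#' @useDynLib fatemap, .registration = TRUE
#' @importFrom stats runif quantile prcomp hclust cutree dist cov qchisq
#'   mahalanobis median sd var predict setNames qnorm
#' @importFrom utils read.csv write.csv write.table
NULL

#' Define an ODE network model
#'
#' A model definition bundles everything the perturbation pipeline needs to
#' know about a dynamical system: the ordered state and parameter names, the
#' basal (reference) parameter values, the default perturbation interval of
#' each parameter, and evaluators for the right-hand side and its Jacobian.
#'
#' @param name Model identifier.
#' @param state_names Character vector of the m state variable names.
#' @param param_names Character vector of the s parameter names.
#' @param basal_values Numeric vector of length s; reference parameter values.
#' @param perturb_intervals s x 2 matrix of (low, high) sampling bounds.
#' @param rhs Function `(state, params) -> m-vector` of time derivatives.
#' @param jacobian Optional function `(state, params) -> m x m matrix`. When
#'   `NULL`, a central finite-difference Jacobian of `rhs` is used.
#' @param ic_range Numeric vector of length m: upper bound of the uniform
#'   range from which random initial conditions are drawn per variable.
#' @param dll Optional list with entries `dllname`, `func`, `initfunc` naming
#'   compiled derivative routines used by the integrator for speed; the R
#'   `rhs` must implement the identical map.
#' @param units Optional named character vector documenting parameter units.
#'
#' @return An object of class `fate_model`.
#' @export
fate_model <- function(name, state_names, param_names, basal_values,
                       perturb_intervals, rhs, jacobian = NULL,
                       ic_range = NULL, dll = NULL, units = NULL) {
  s <- length(param_names)
  m <- length(state_names)
  basal_values <- as.numeric(basal_values)
  perturb_intervals <- as.matrix(perturb_intervals)
  if (length(basal_values) != s)
    stop("basal_values must have one entry per parameter (", s, ")")
  if (!all(dim(perturb_intervals) == c(s, 2)))
    stop("perturb_intervals must be an s x 2 matrix")
  if (any(perturb_intervals[, 1] >= perturb_intervals[, 2]))
    stop("every perturbation interval needs low < high")
  dimnames(perturb_intervals) <- list(param_names, c("low", "high"))
  names(basal_values) <- param_names
  if (is.null(ic_range)) ic_range <- rep(1, m)
  if (is.null(jacobian)) {
    rhs_local <- rhs
    jacobian <- function(state, params) {
      num_jacobian(function(y) rhs_local(y, params), state)
    }
  }
  structure(
    list(name = name, state_names = state_names, param_names = param_names,
         basal_values = basal_values, perturb_intervals = perturb_intervals,
         rhs = rhs, jacobian = jacobian, ic_range = ic_range, dll = dll,
         units = units),
    class = "fate_model")
}

#' @export
print.fate_model <- function(x, ...) {
  cat("<fate_model> ", x$name, "\n", sep = "")
  cat("  states (", length(x$state_names), "): ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  parameters (", length(x$param_names), "): ",
      paste(x$param_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Evaluate the right-hand side of a model
#'
#' Pure, deterministic evaluation of the time-derivative vector.
#'
#' @param model A [fate_model()].
#' @param state Numeric m-vector.
#' @param params Numeric s-vector in model parameter order.
#' @return Numeric m-vector of derivatives.
#' @export
evaluate_rhs <- function(model, state, params) {
  if (length(state) != length(model$state_names))
    stop("state has length ", length(state), " but model '", model$name,
         "' has ", length(model$state_names), " state variables")
  if (length(params) != length(model$param_names))
    stop("params has length ", length(params), " but model '", model$name,
         "' has ", length(model$param_names), " parameters")
  model$rhs(as.numeric(state), as.numeric(params))
}

#' Evaluate the Jacobian of a model
#'
#' @inheritParams evaluate_rhs
#' @return m x m matrix of partial derivatives of the right-hand side.
#' @export
evaluate_jacobian <- function(model, state, params) {
  J <- model$jacobian(as.numeric(state), as.numeric(params))
  if (any(!is.finite(J))) stop("non-finite Jacobian at the supplied state")
  J
}

# central finite-difference Jacobian; step scaled to the state magnitude
num_jacobian <- function(f, y, rel_h = 1e-6) {
  m <- length(y)
  f0 <- f(y)
  J <- matrix(0, length(f0), m)
  for (j in seq_len(m)) {
    h <- rel_h * max(1, abs(y[j]))
    e <- numeric(m); e[j] <- h
    J[, j] <- (f(y + e) - f(y - e)) / (2 * h)
  }
  J
}

# shifted Hill repression: full activity 1 at x = 0, floor lambda as x -> Inf
shifted_hill <- function(x, k, n, lambda) {
  ifelse(x <= 0, 1, lambda + (1 - lambda) / (1 + (x / k)^n))
}

#' The mutual-inhibition toggle switch
#'
#' Two proteins A and B repress each other's production through shifted Hill
#' kinetics and decay with first-order kinetics:
#' \deqn{dA/dt = g_a H(B; k_a, n_a, \lambda_a) - A/\tau_a}
#' \deqn{dB/dt = g_b H(A; k_b, n_b, \lambda_b) - B/\tau_b}
#' with \eqn{H(x) = \lambda + (1-\lambda)/(1+(x/k)^n)}. Production rates
#' `ga`, `gb` are in nmol l^-1 h^-1, thresholds `ka`, `kb` in nmol l^-1,
#' timescales `tau_a`, `tau_b` in h; the fold changes `lambda_a`, `lambda_b`
#' and Hill coefficients `na`, `nb` are dimensionless. The circuit is the
#' canonical bistable motif: both states have one dominant protein, state I
#' (B high, A low) and state III (A high, B low).
#'
#' Basal values place the switch inside its bistable regime: with the default
#' production interval \[50, 80\] for `ga`, `gb`, about a quarter of uniformly
#' drawn (`ga`, `gb`) pairs support two coexisting stable states, and at
#' `gb = 70` a bistable window in `ga` opens and closes inside \[50, 80\].
#'
#' @return A [fate_model()] with 2 state variables and 10 parameters.
#' @export
toggle_switch_model <- function() {
  pnames <- c("ga", "gb", "tau_a", "tau_b", "ka", "kb",
              "lambda_a", "lambda_b", "na", "nb")
  basal <- c(ga = 65, gb = 65, tau_a = 1, tau_b = 1, ka = 24, kb = 24,
             lambda_a = 0.275, lambda_b = 0.275, na = 4, nb = 4)
  intervals <- cbind(low  = 0.75 * basal, high = 1.25 * basal)
  intervals[c("ga", "gb"), ] <- rep(c(50, 80), each = 2)
  rhs <- function(state, params) .Call(C_ts_rhs, state, params)
  jac <- function(state, params) {
    p <- params
    dH <- function(x, k, n, lambda) {
      if (x <= 0) return(0)
      u <- (x / k)^n
      -(1 - lambda) * n * u / (x * (1 + u)^2)
    }
    matrix(c(-1 / p[3],                      p[1] * dH(state[2], p[5], p[9], p[7]),
             p[2] * dH(state[1], p[6], p[10], p[8]), -1 / p[4]),
           2, 2, byrow = TRUE)
  }
  fate_model(
    name = "toggle_switch",
    state_names = c("A", "B"),
    param_names = pnames,
    basal_values = basal,
    perturb_intervals = intervals,
    rhs = rhs, jacobian = jac,
    ic_range = c(120, 120),
    dll = list(dllname = "fatemap", func = "fatemap_ts_derivs",
               initfunc = "fatemap_ts_init"),
    units = c(ga = "nmol l-1 h-1", gb = "nmol l-1 h-1", tau_a = "h",
              tau_b = "h", ka = "nmol l-1", kb = "nmol l-1",
              lambda_a = "1", lambda_b = "1", na = "1", nb = "1"))
}

# EMT basal parameter vector, shared by emt_model() and documentation
emt_basal_values <- function() {
  c(TGF0 = 1.5, kT = 0.4,
    ks = 1.0, kS = 1.0, k3 = 0.5, kz = 1.0, kZ = 1.0, k2 = 0.5,
    ke1 = 0.5, ke2 = 0.5, kn1 = 0.5, kn2 = 0.5,
    kdT = 0.5, kds = 0.5, kdS = 0.5, kd3 = 0.5, kdz = 0.5, kdZ = 0.5,
    kd2 = 0.5, kde = 0.5, kdn = 0.5,
    JT = 0.3, Js = 1.30, Jss = 2.0, JS = 0.18, J31 = 0.25, J32 = 0.5,
    Jz = 2.45, JZ = 0.2, J21 = 2.0, J22 = 0.2, Je1 = 0.8, Je2 = 0.5,
    Jn1 = 0.8, Jn2 = 0.5,
    nT = 2, ns = 2, nS = 2, n3 = 2, nz = 4, nZ = 2, n2 = 2, ne = 2, nn = 2)
}

#' The core EMT regulatory network
#'
#' Nine state variables -- endogenous TGF-beta (`T`), snail mRNA (`s`), SNAIL
#' protein (`S`), miR-34 (`R3`), zeb mRNA (`z`), ZEB protein (`Z`), miR-200
#' (`R2`), E-cadherin (`E`) and N-cadherin (`N`) -- wired as two coupled
#' double-negative switches. Total TGF-beta (endogenous plus the exogenous
#' dose `TGF0`) activates snail transcription; SNAIL and miR-34 repress each
#' other (first switch), SNAIL activates zeb, and ZEB and miR-200 repress
#' each other (second switch); miR-200 also represses endogenous TGF-beta
#' production, closing a positive feedback. E-cadherin is produced under
#' repression by SNAIL and ZEB; N-cadherin is activated by both. All 44
#' parameters (production rates `k*` in uM/h, degradation rates `kd*` in 1/h,
#' Hill thresholds `J*` in uM, Hill coefficients `n*`, and the exogenous dose
#' `TGF0` in uM) are sampled; by default each within 75-125 percent of its basal
#' value, except `TGF0` in \[0, 3\] and `kT` in \[0.3, 0.5\] uM/h, the window
#' across which the epithelial / hybrid / mesenchymal transition unfolds and
#' parameter sets with three coexisting stable states occur.
#'
#' The staggered thresholds of the two switches create a stable hybrid E/M
#' branch (SNAIL high, ZEB still low) between the epithelial state (both
#' switches off: E-cadherin high) and the mesenchymal state (both on:
#' N-cadherin high).
#'
#' @return A [fate_model()] with 9 state variables and 44 parameters.
#' @export
emt_model <- function() {
  basal <- emt_basal_values()
  intervals <- cbind(low = 0.75 * basal, high = 1.25 * basal)
  intervals["TGF0", ] <- c(0, 3)
  intervals["kT", ] <- c(0.3, 0.5)
  rhs <- function(state, params) .Call(C_emt_rhs, state, params)
  fate_model(
    name = "emt",
    state_names = c("T", "s", "S", "R3", "z", "Z", "R2", "E", "N"),
    param_names = names(basal),
    basal_values = basal,
    perturb_intervals = intervals,
    rhs = rhs,
    ic_range = c(3, 3, 4, 1.5, 3, 4, 1.5, 2.5, 2.5),
    dll = list(dllname = "fatemap", func = "fatemap_emt_derivs",
               initfunc = "fatemap_emt_init"))
}

# ---- model registry ----

.model_registry <- new.env(parent = emptyenv())

#' Register a model under its name
#'
#' Registered models can be retrieved by name, which is how run
#' configurations and the command-line runner select them. The two built-in
#' networks are pre-registered; user-defined models plug in through the same
#' [fate_model()] contract.
#'
#' @param model A [fate_model()].
#' @return The model, invisibly.
#' @export
register_model <- function(model) {
  stopifnot(inherits(model, "fate_model"))
  assign(model$name, model, envir = .model_registry)
  invisible(model)
}

#' Retrieve a registered model by name
#' @param name Model name.
#' @return A [fate_model()].
#' @export
get_model <- function(name) {
  if (!exists(name, envir = .model_registry))
    stop("unknown model '", name, "'; registered: ",
         paste(list_models(), collapse = ", "))
  get(name, envir = .model_registry)
}

#' List registered model names
#' @return Character vector.
#' @export
list_models <- function() sort(ls(envir = .model_registry))

.onLoad <- function(libname, pkgname) {
  register_model(toggle_switch_model())
  register_model(emt_model())
}

#' Export a model description to JSON
#'
#' Writes the declarative part of a model (names, basal values, perturbation
#' intervals, units) as structured text; the rate equations remain code.
#'
#' @param model A [fate_model()].
#' @param path File path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
export_model_json <- function(model, path = NULL) {
  obj <- list(name = model$name,
              state_names = model$state_names,
              param_names = model$param_names,
              basal_values = as.list(model$basal_values),
              perturb_intervals = apply(model$perturb_intervals, 1, as.list),
              ic_range = model$ic_range,
              units = as.list(model$units))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
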
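# Shared fixtures and independent oracles.

# linear decay network: dx_i/dt = a_i - k_i * x_i, closed-form steady state a/k
linear_decay_model <- function(m = 2) {
  pnames <- c(paste0("a", seq_len(m)), paste0("k", seq_len(m)))
  basal <- c(rep(2, m), rep(4, m))
  fate_model(
    name = paste0("linear_decay_", m),
    state_names = paste0("x", seq_len(m)),
    param_names = pnames,
    basal_values = basal,
    perturb_intervals = cbind(0.5 * basal, 1.5 * basal),
    rhs = function(state, params) {
      a <- params[seq_len(m)]
      k <- params[m + seq_len(m)]
      a - k * state
    },
    ic_range = rep(2, m))
}

# one-variable models with known stability, for the stability labeller
decaying_model <- fate_model(
  name = "decay1", state_names = "x", param_names = "r",
  basal_values = 1, perturb_intervals = cbind(0.5, 2),
  rhs = function(state, params) -params[1] * state, ic_range = 1)

growing_model <- fate_model(
  name = "grow1", state_names = "x", param_names = "r",
  basal_values = 1, perturb_intervals = cbind(0.5, 2),
  rhs = function(state, params) params[1] * state, ic_range = 1)

# Independent toggle-switch oracle: the steady states satisfy
#   A = ga ta H(B), B = gb tb H(A),
# so every state is a root of g(B) = gb tb H(ga ta H(B)) - B. Roots are
# enumerated by sign changes on a dense grid and bisection; a root is a
# stable node exactly when g crosses zero downwards (the trace of the
# Jacobian is always negative, and det > 0 <=> g'(B) < 0 ... with
# g(B) = RHS(B) - B, downward crossing means d RHS/dB < 1, i.e. det > 0).
ts_oracle_states <- function(params, grid_n = 2000) {
  ga <- params[1]; gb <- params[2]; ta <- params[3]; tb <- params[4]
  ka <- params[5]; kb <- params[6]; la <- params[7]; lb <- params[8]
  na <- params[9]; nb <- params[10]
  H <- function(x, k, n, l) l + (1 - l) / (1 + (x / k)^n)
  g <- function(B) gb * tb * H(ga * ta * H(B, ka, na, la), kb, nb, lb) - B
  Bs <- seq(0, gb * tb * 1.0001, length.out = grid_n)
  gs <- g(Bs)
  states <- NULL
  for (i in seq_len(grid_n - 1)) {
    if (gs[i] > 0 && gs[i + 1] <= 0) {   # downward crossing -> stable
      root <- uniroot(g, c(Bs[i], Bs[i + 1]), tol = 1e-12)$root
      A <- ga * ta * H(root, ka, na, la)
      states <- rbind(states, c(A = A, B = root))
    }
  }
  states[order(states[, 1]), , drop = FALSE]
}

# dominant protein as a fate oracle for toggle-switch states
ts_dominance <- function(X) ifelse(X[, "A"] > X[, "B"], "III", "I")

# central-difference Jacobian used as an oracle against model Jacobians
fd_jacobian <- function(f, y, h = 1e-6) {
  m <- length(y)
  J <- matrix(0, length(f(y)), m)
  for (j in seq_len(m)) {
    e <- numeric(m); e[j] <- h * max(1, abs(y[j]))
    J[, j] <- (f(y + e) - f(y - e)) / (2 * e[j])
  }
  J
}
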
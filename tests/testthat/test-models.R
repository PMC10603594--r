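test_that("toggle switch respects its A<->B exchange symmetry", {
  ts <- toggle_switch_model()
  p <- ts$basal_values  # a- and b-parameters are equal at basal
  for (x in c(5, 20, 60)) {
    d <- evaluate_rhs(ts, c(x, x), p)
    expect_equal(d[1], d[2])
  }
  # swapping (A,B) with swapped parameter roles mirrors the field
  p_swap <- p[c("gb", "ga", "tau_b", "tau_a", "kb", "ka",
                "lambda_b", "lambda_a", "nb", "na")]
  d1 <- evaluate_rhs(ts, c(10, 40), p)
  d2 <- evaluate_rhs(ts, c(40, 10), unname(p_swap))
  expect_equal(d1, rev(d2))
})

test_that("rhs evaluation validates dimensions with a named error", {
  ts <- toggle_switch_model()
  expect_error(evaluate_rhs(ts, c(1, 2, 3), ts$basal_values), "state")
  expect_error(evaluate_rhs(ts, c(1, 2), ts$basal_values[-1]), "params")
})

test_that("model Jacobians match central finite differences", {
  ts <- toggle_switch_model()
  emt <- emt_model()
  set.seed(42)
  for (i in 1:100) {
    p <- runif(10, ts$perturb_intervals[, 1], ts$perturb_intervals[, 2])
    y <- runif(2, 1, 100)
    J <- evaluate_jacobian(ts, y, p)
    J_fd <- fd_jacobian(function(s) evaluate_rhs(ts, s, p), y)
    expect_lt(max(abs(J - J_fd)) / max(abs(J_fd)), 1e-4)
  }
  set.seed(43)
  for (i in 1:20) {
    p <- runif(44, emt$perturb_intervals[, 1], emt$perturb_intervals[, 2])
    y <- runif(9, 0.05, 2)
    J <- evaluate_jacobian(emt, y, p)
    J_fd <- fd_jacobian(function(s) evaluate_rhs(emt, s, p), y)
    expect_lt(max(abs(J - J_fd)) / max(abs(J_fd)), 1e-4)
  }
})

test_that("EMT right-hand side is finite and real on nonnegative states", {
  emt <- emt_model()
  set.seed(1)
  for (i in 1:50) {
    y <- runif(9, 0, 5)
    d <- evaluate_rhs(emt, y, emt$basal_values)
    expect_true(all(is.finite(d)))
    expect_true(is.numeric(d) && length(d) == 9)
  }
  # concentrations cannot be driven negative from zero
  d0 <- evaluate_rhs(emt, rep(0, 9), emt$basal_values)
  expect_true(all(d0 >= 0))
})

test_that("a bistable window in ga opens and closes inside [50, 80] at gb = 70", {
  ts <- toggle_switch_model()
  p <- ts$basal_values
  p["gb"] <- 70
  counts <- vapply(seq(50, 80, by = 1.5), function(ga) {
    p["ga"] <- ga
    nrow(ts_oracle_states(p))
  }, 0)
  expect_equal(counts[1], 1)                  # monostable at ga = 50
  expect_equal(counts[length(counts)], 1)     # monostable at ga = 80
  expect_true(any(counts == 2))               # bistable window in between
  # the window is contiguous: counts go 1 -> 2 -> 1
  r <- rle(counts)
  expect_equal(r$values, c(1, 2, 1))
})

test_that("integration from nonnegative states stays nonnegative", {
  for (model in list(toggle_switch_model(), emt_model())) {
    set.seed(7)
    ics <- matrix(runif(3 * length(model$ic_range)), 3) %*%
      diag(model$ic_range, length(model$ic_range))
    for (i in 1:3) {
      ss <- find_steady_states(model, model$basal_values, seed = i,
                               control = ss_control(n_starts = 2))
      expect_true(all(ss$states >= -1e-8))
    }
  }
})

test_that("the model registry resolves built-ins and rejects unknowns", {
  expect_true(all(c("toggle_switch", "emt") %in% list_models()))
  expect_s3_class(get_model("emt"), "fate_model")
  expect_error(get_model("nonexistent"), "unknown model")
  custom <- linear_decay_model()
  register_model(custom)
  expect_identical(get_model(custom$name)$name, custom$name)
})

test_that("model export writes valid structured JSON", {
  path <- tempfile(fileext = ".json")
  export_model_json(toggle_switch_model(), path)
  obj <- jsonlite::fromJSON(path)
  expect_equal(obj$name, "toggle_switch")
  expect_equal(length(obj$param_names), 10)
  expect_equal(unname(unlist(obj$basal_values["ga"])), 65)
})

test_that("raising exogenous TGF-beta drives the EMT from E- to N-cadherin dominance", {
  emt <- emt_model()
  p <- emt$basal_values
  y <- c(0.1, 0.1, 0.1, 1, 0.1, 0.1, 1, 2, 0)   # epithelial-like start
  levels <- NULL
  for (tg in seq(0, 3, by = 0.5)) {             # follow the branch upward
    p["TGF0"] <- tg
    out <- deSolve::lsoda(y, c(0, 2000),
                          function(t, s, pp) list(evaluate_rhs(emt, s, p)),
                          NULL, rtol = 1e-8, atol = 1e-10)
    y <- as.numeric(out[nrow(out), -1])
    levels <- rbind(levels, c(E = y[8], N = y[9]))
  }
  expect_gt(levels[1, "E"], levels[1, "N"])                 # E-dominant at 0
  expect_gt(levels[nrow(levels), "N"], levels[nrow(levels), "E"])  # N at 3
})

test_that("the EMT window admits three coexisting stable states", {
  emt <- emt_model()
  p <- emt$basal_values
  p["TGF0"] <- 1.3
  p["kT"] <- 0.5
  ss <- find_steady_states(emt, p, seed = 3,
                           control = ss_control(n_starts = 60))
  expect_gte(ss$n_states, 3)
  # the three states are E-like, hybrid, and M-like by N-cadherin level
  N <- sort(ss$states[, "N"])
  expect_lt(N[1], 0.2)
  expect_true(N[2] > 0.4 && N[2] < 1.1)
  expect_gt(N[3], 1.2)
})
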
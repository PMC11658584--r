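test_that("the controlled dynamics reduce to the uncontrolled model at u = 0", {
  set.seed(21)
  for (i in 1:20) {
    y <- random_state()
    expect_lte(max(abs(controlled_rhs(0, y, rep(0, 5), bp) -
                         model_rhs(0, y, bp))), 1e-15)
  }
})

test_that("full prevention shuts off recruitment into the habit compartments", {
  y <- initial_state()
  u <- c(1, 1, 0, 0.3, 0)
  dy <- controlled_rhs(0, y, u, bp)
  rD <- bp[["mu"]] + bp[["phi1"]] + bp[["delta1"]] + u[4]
  expect_equal(dy[["D"]], -rD * y[["D"]], tolerance = 1e-14)
  expect_equal(dy[["M"]],
               -(bp[["mu"]] + bp[["phi2"]] + bp[["delta2"]]) * y[["M"]],
               tolerance = 1e-14)
  expect_equal(dy[["Dm"]],
               -(bp[["mu"]] + bp[["phi3"]] + bp[["k1"]]) * y[["Dm"]],
               tolerance = 1e-14)
  expect_error(controlled_rhs(0, y, c(1.2, 0, 0, 0, 0), bp),
               "out of bounds")
})

test_that("controls only move individuals between compartments", {
  set.seed(8)
  for (i in 1:20) {
    y <- random_state()
    u <- runif(5)
    dy <- controlled_rhs(0, y, u, bp)
    expected <- bp[["xi"]] - bp[["mu"]] * sum(y) - bp[["phi1"]] * y[["D"]] -
      bp[["phi2"]] * y[["M"]] - bp[["phi3"]] * y[["Dm"]]
    expect_equal(sum(dy), expected, tolerance = 1e-12)
  }
})

test_that("the objective integrates the quadratic running cost correctly", {
  times <- seq(0, 52, 0.5)
  n <- length(times)
  zero <- list(times = times, states = matrix(0, n, 7))
  w <- objective_weights()
  expect_equal(control_objective(zero, matrix(0, n, 5), w), 0)
  constD <- list(times = times,
                 states = cbind(0, 1, 0, 0, 0, 0, 0)[rep(1, n), ])
  expect_equal(control_objective(constD, NULL, w), 5200)  # 100 * 52
  u1 <- cbind(1, 0, 0, 0, 0)[rep(1, n), ]
  expect_equal(control_objective(zero, u1, w), 13)  # 0.5*0.5*52
  expect_error(control_objective(zero, matrix(0, 3, 5), w),
               "grid mismatch")
  expect_error(objective_weights(A1 = 0), "positive")
})

test_that("the Hamiltonian couples cost and dynamics as specified", {
  set.seed(13)
  y <- random_state()
  u <- runif(5, 0.1, 0.9)
  l <- runif(7, -2, 2)
  w <- objective_weights()
  # with zero adjoints H is the running cost alone
  integrand <- 100 * y[["D"]] + 100 * y[["M"]] + 100 * y[["Dm"]] +
    0.5 * sum(0.5 * u^2)
  expect_equal(hamiltonian(y, u, rep(0, 7), bp, w), integrand,
               tolerance = 1e-12)
  expect_equal(hamiltonian(y, u, l, bp, w),
               integrand + sum(l * controlled_rhs(0, y, u, bp)),
               tolerance = 1e-12)
  # quadratic in each control: second difference equals w_k
  h <- 0.05
  for (k in 1:5) {
    up <- u; um <- u
    up[k] <- u[k] + h
    um[k] <- u[k] - h
    second <- (hamiltonian(y, up, l, bp, w) -
                 2 * hamiltonian(y, u, l, bp, w) +
                 hamiltonian(y, um, l, bp, w)) / h^2
    expect_equal(second, 0.5, tolerance = 1e-7)
  }
})

test_that("adjoint derivatives equal minus the Hamiltonian state gradient", {
  set.seed(17)
  w <- objective_weights()
  worst <- 0
  for (i in 1:100) {
    y <- random_state()
    u <- runif(5, 0.05, 0.95)
    l <- runif(7, -2, 2)
    err <- max(abs(adjoint_rhs(y, u, l, bp, w) -
                     fd_adjoint(y, u, l, bp, w)))
    worst <- max(worst, err)
  }
  expect_lte(worst, 1e-8)
})

test_that("adjoint structure: running-cost sources and relapse couplings", {
  w <- objective_weights()
  expect_equal(unname(adjoint_rhs(rep(0, 7), rep(0, 5), rep(0, 7), bp, w)),
               c(0, -100, -100, -100, 0, 0, 0))
  # dlambda5/dt couples lambda5 (not lambda4) to the Rd relapse flow
  l5 <- c(0, 0, 0, 0, 1, 0, 0)
  expect_equal(adjoint_rhs(initial_state(), rep(0, 5), l5, bp,
                           w)[["lambda5"]],
               bp[["mu"]] + bp[["gamma1"]])
  # dlambda7/dt decays at mu + gamma3 and feeds from lambda1 * gamma3
  l7 <- c(0, 0, 0, 0, 0, 0, 1)
  expect_equal(adjoint_rhs(initial_state(), rep(0, 5), l7, bp,
                           w)[["lambda7"]],
               bp[["mu"]] + bp[["gamma3"]])
  l1 <- c(1, 0, 0, 0, 0, 0, 0)
  d <- adjoint_rhs(initial_state(), rep(0, 5), l1, bp, w)
  expect_equal(d[["lambda7"]], -bp[["gamma3"]])
  expect_equal(d[["lambda6"]], -bp[["gamma2"]])
})

test_that("characterized controls are clamped stationary points of H", {
  w <- objective_weights()
  expect_equal(unname(update_controls(initial_state(), rep(0, 7), bp, w)),
               rep(0, 5))
  # an enormous adjoint on D pushes the drinker-treatment control to 1
  lbig <- c(0, 1e6, 0, 0, 0, 0, 0)
  expect_equal(update_controls(initial_state(), lbig, bp, w)[["u4"]], 1)
  # interior values satisfy |dH/du| <= 1e-8
  set.seed(23)
  for (i in 1:30) {
    y <- random_state()
    l <- runif(7, -0.5, 0.5)
    u <- update_controls(y, l, bp, w)
    grad <- fd_hamiltonian_du(y, pmin(pmax(u, 0.01), 0.99), l, bp, w)
    interior <- u > 0.011 & u < 0.989
    if (any(interior))
      expect_lte(max(abs(grad[interior])), 1e-8)
  }
  expect_error(update_controls(initial_state(), rep(0, 7), bp,
                               objective_weights(),
                               bounds = control_bounds(upper = 2)),
               "bounds")
})

test_that("with no state cost the optimal policy is to do nothing", {
  w <- objective_weights(A1 = 1e-12, A2 = 1e-12, A3 = 1e-12)
  # weights must be positive; drive them to numerical zero instead
  sol <- optimal_control(bp, horizon = 5, step = 0.05, weights = w)
  expect_true(sol$converged)
  expect_lte(max(abs(sol$controls)), 1e-10)
  expect_lte(sol$objective, 1e-10)
})

test_that("zero-width bounds reproduce the uncontrolled trajectory exactly", {
  sol <- optimal_control(bp, horizon = 5, step = 0.05,
                         bounds = control_bounds(enabled = integer(0)))
  expect_equal(sol$states, sol$baseline$states, tolerance = 1e-12)
  expect_equal(sol$objective, sol$objective_uncontrolled,
               tolerance = 1e-12)
})

test_that("every iterate respects the control box and transversality", {
  sol <- optimal_control(bp, horizon = 10, step = 0.02)
  expect_true(all(sol$controls >= 0 & sol$controls <= 1))
  expect_equal(unname(sol$adjoints[nrow(sol$adjoints), ]), rep(0, 7))
  expect_true(sol$converged)
  expect_lt(sol$objective, sol$objective_uncontrolled)
  expect_equal(nrow(sol$log), sol$iterations)
})

test_that("a converged solution admits no improving single-control perturbation", {
  sol <- optimal_control(bp, horizon = 10, step = 0.01, tol = 1e-8,
                         max_iter = 1000)
  expect_true(sol$converged)
  chk <- check_local_optimality(sol, delta = 0.01, n_intervals = 10)
  expect_gte(min(chk$delta_J), -1e-6)
})

test_that("raising the drinker state cost never raises the drinker burden", {
  s1 <- optimal_control(bp, horizon = 10, step = 0.02,
                        weights = objective_weights(A1 = 10))
  s2 <- optimal_control(bp, horizon = 10, step = 0.02,
                        weights = objective_weights(A1 = 100))
  intD <- function(s) codepend:::.trapz(s$times, s$states[, "D"])
  expect_lte(intD(s2), intD(s1) + 1e-9)
})

test_that("efficacy trajectories obey their defining identities", {
  times <- seq(0, 10, 0.5)
  n <- length(times)
  base <- list(times = times,
               states = matrix(rep(c(1, 0.5, 0.2, 0.1, 0, 0, 0), each = n),
                               n, 7, dimnames = list(NULL, names(initial_state()))))
  expect_equal(control_efficacy(base, base, "D"), rep(0, n))
  ctrl <- base
  ctrl$states[, 2] <- 0
  expect_equal(control_efficacy(ctrl, base, "D"), rep(1, n))
  zero_base <- base
  zero_base$states[, 2] <- 0
  expect_true(all(is.na(control_efficacy(ctrl, zero_base, "D"))))
  bad <- base
  bad$times <- times + 1
  expect_error(control_efficacy(ctrl, bad, "D"), "grid mismatch")
})
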
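test_that("closed-form reproduction numbers match hand arithmetic", {
  expect_equal(r0_drinkers(bp), 0.3912567272, tolerance = 1e-9)
  expect_equal(r0_smokers(bp), 0.6036897518, tolerance = 1e-9)
  expect_equal(r0_drinkers(model_params(a1 = 0)), 0)
  expect_equal(r0_smokers(model_params(a2 = 0)), 0)
  # linear in the contact rate
  expect_equal(r0_drinkers(model_params(a1 = 2 * 0.00479)),
               2 * r0_drinkers(bp))
  # R0M ignores the drinking-side rates entirely
  p <- model_params(a1 = 0.3, delta1 = 0.9, phi1 = 0.2, gamma1 = 0.1,
                    k1 = 0.5, assume_identities = FALSE)
  expect_equal(r0_smokers(p), r0_smokers(bp))
})

test_that("next-generation spectrum reduces to the submodel closed forms", {
  r0 <- reproduction_numbers(bp)
  ev <- sort(Re(r0$eigenvalues), decreasing = TRUE)
  expect_lt(max(abs(Im(r0$eigenvalues))), 1e-14)
  expect_equal(ev, sort(c(r0_drinkers(bp), r0_smokers(bp), 0),
                        decreasing = TRUE),
               tolerance = 1e-12)
  expect_equal(r0$r0_codependence, max(r0$r0_drinkers, r0$r0_smokers),
               tolerance = 1e-12)
  # degenerate and symmetric cases
  expect_equal(reproduction_numbers(
    model_params(a1 = 0, a2 = 0))$r0_codependence, 0)
  ps <- model_params(a1 = 0.035, a2 = 0.035, phi1 = 0.01, phi2 = 0.01,
                     delta1 = 0.1, delta2 = 0.1,
                     assume_identities = FALSE)
  evs <- Re(reproduction_numbers(ps)$eigenvalues)
  top2 <- sort(evs, decreasing = TRUE)[1:2]
  expect_equal(top2[1], top2[2], tolerance = 1e-12)
})

test_that("spectral radius equals the larger submodel R0 across random sets", {
  for (p in random_params(40, seed = 202)) {
    expect_equal(reproduction_numbers(p)$r0_codependence,
                 max(r0_drinkers(p), r0_smokers(p)), tolerance = 1e-10)
  }
})

test_that("submodel habit-free equilibria sit at S = xi/mu with zero residual", {
  dr <- drinker_equilibria(bp)
  expect_equal(dr$free$state[["S"]], 8.4033613445, tolerance = 1e-9)
  expect_lte(dr$free$residual, 1e-10)
  expect_true(dr$free$locally_stable)  # R0D < 1 at baseline
  expect_true(dr$free$r0_consistent)
  sm <- smoker_equilibria(bp)
  expect_equal(sm$free$state[["S"]], 8.4033613445, tolerance = 1e-9)
  expect_true(sm$free$r0_consistent)
})

test_that("endemic closed forms satisfy the steady-state equations when R0 > 1", {
  # contact rates scaled so R0 = 2 in each submodel (hand arithmetic)
  pd <- model_params(a1 = 0.024485202)
  dr <- drinker_equilibria(pd)
  expect_true(dr$endemic$admissible)
  expect_true(all(dr$endemic$state[c("S", "D", "Rd")] > 0))
  expect_lte(dr$endemic$residual, 1e-10)
  expect_true(dr$endemic$locally_stable)
  ps <- model_params(a2 = 0.1159536)
  sm <- smoker_equilibria(ps)
  expect_true(sm$endemic$admissible)
  expect_lte(sm$endemic$residual, 1e-10)
})

test_that("without relapse the endemic drinker level has a two-term closed form", {
  p <- model_params(a1 = 0.024485202, gamma1 = 0, gamma3 = 0,
                    assume_identities = FALSE)
  dr <- drinker_equilibria(p)
  q <- p[["mu"]] + p[["phi1"]] + p[["delta1"]]
  expect_equal(dr$endemic$state[["D"]],
               p[["xi"]] / q - p[["mu"]] / p[["a1"]], tolerance = 1e-12)
})

test_that("the endemic equilibrium is inadmissible below threshold", {
  dr <- drinker_equilibria(bp)  # R0D = 0.39 < 1
  expect_false(dr$endemic$admissible)
  expect_error(drinker_equilibria(bp, strict = TRUE), "D")
})

test_that("drinker and smoker submodels are images of each other under rate swap", {
  p1 <- model_params(a1 = 0.03, delta1 = 0.1, phi1 = 0.02, gamma1 = 0.4,
                     a2 = 0.001, delta2 = 0.2, phi2 = 0.01, gamma2 = 0.1,
                     assume_identities = FALSE)
  p2 <- model_params(a2 = 0.03, delta2 = 0.1, phi2 = 0.02, gamma2 = 0.4,
                     a1 = 0.001, delta1 = 0.2, phi1 = 0.01, gamma1 = 0.1,
                     assume_identities = FALSE)
  d <- drinker_equilibria(p1)$endemic
  s <- smoker_equilibria(p2)$endemic
  expect_equal(unname(d$state[c("S", "D", "Rd")]),
               unname(s$state[c("S", "M", "Rm")]), tolerance = 1e-12)
})

test_that("the analytic Jacobian matches finite differences of the dynamics", {
  set.seed(5)
  for (i in 1:10) {
    y <- random_state()
    J <- model_jacobian(y, bp)
    h <- 1e-6
    Jfd <- vapply(1:7, function(j) {
      yp <- y; ym <- y
      yp[j] <- y[j] + h
      ym[j] <- y[j] - h
      (model_rhs(0, yp, bp) - model_rhs(0, ym, bp)) / (2 * h)
    }, numeric(7))
    expect_lt(max(abs(J - Jfd)), 1e-6)
  }
})

test_that("with no contacts or relapse the Jacobian is lower triangular", {
  p <- model_params(a1 = 0, a2 = 0, gamma1 = 0, gamma2 = 0, gamma3 = 0,
                    assume_identities = FALSE)
  J <- model_jacobian(initial_state(), p)
  expect_equal(max(abs(J[upper.tri(J)])), 0)
  expect_equal(unname(diag(J)),
               -c(p[["mu"]],
                  p[["mu"]] + p[["phi1"]] + p[["delta1"]],
                  p[["mu"]] + p[["phi2"]] + p[["delta2"]],
                  p[["mu"]] + p[["phi3"]] + p[["k1"]],
                  rep(p[["mu"]], 3)))
})

test_that("the habit-free spectrum contains the five known decay rates", {
  sr <- stability_report(bp)
  ev <- sort(Re(sr$eigenvalues))
  known <- c(-0.0952, -0.7952, -0.10095, -0.448075, -0.289439)
  for (k in known)
    expect_lt(min(abs(ev - k)), 1e-9)
  expect_true(sr$locally_stable)
  expect_true(sr$r0_consistent)
})

test_that("destabilising one habit flips the verdict consistently", {
  # a2 scaled so R0M = 1.5
  p <- model_params(a2 = 1.5 * 0.0952 * 0.4872 / 0.8)
  sr <- stability_report(p)
  expect_false(sr$locally_stable)
  expect_true(sr$r0_consistent)
  # exactly at threshold a zero eigenvalue makes the verdict marginal
  pm <- model_params(a2 = 0.0952 * 0.4872 / 0.8)
  srm <- stability_report(pm)
  expect_equal(srm$verdict, "marginal")
  expect_lt(min(abs(Re(srm$eigenvalues))), 1e-10)
})

test_that("eigenvalue verdict and R0 threshold agree across random parameter sets", {
  for (p in random_params(200, seed = 99)) {
    sr <- stability_report(p)
    if (sr$verdict == "marginal") next
    expect_equal(sr$locally_stable,
                 max(sr$r0_drinkers, sr$r0_smokers) < 1,
                 info = paste(round(unclass(p), 5), collapse = ","))
  }
})

test_that("long submodel runs converge to the endemic closed form when R0 > 1", {
  pd <- model_params(a1 = 0.024485202)
  target <- drinker_equilibria(pd)$endemic$state
  y0 <- model_state(S = 0.6, D = 0.2, Rd = 0.02)
  tr <- simulate_model(pd, y0, horizon = 2000, step = 0.05)
  expect_lt(max(abs(tr$states[nrow(tr$states), ] - target)), 1e-4)
  ps <- model_params(a2 = 0.1159536)
  target_s <- smoker_equilibria(ps)$endemic$state
  y0s <- model_state(S = 0.6, M = 0.1, Rm = 0.01)
  trs <- simulate_model(ps, y0s, horizon = 2000, step = 0.05)
  expect_lt(max(abs(trs$states[nrow(trs$states), ] - target_s)), 1e-4)
})

test_that("the numerically located full-model endemic state meets the residual contract", {
  # push both habits above threshold
  p <- model_params(a1 = 0.03, a2 = 0.12)
  ee <- endemic_equilibrium(p)
  expect_lte(ee$residual, 1e-10)
  expect_true(all(ee$state > 0))
  expect_true(ee$locally_stable)
})

test_that("below threshold random states are attracted to the habit-free state", {
  d <- attraction_probe(bp, n_states = 20, horizon = 2000, step = 0.05,
                        seed = 7)
  expect_lt(max(d), 1e-4)
})
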
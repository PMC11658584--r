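#' Basic reproduction number of the drinkers-only submodel
#'
#' Closed form `R0D = a1 * xi / (mu * (mu + phi1 + delta1))`: the expected
#' number of new drinkers recruited by one drinker introduced into the
#' wholly susceptible population S = xi / mu.
#'
#' @param params model parameters.
#' @return Dimensionless scalar.
#' @export
r0_drinkers <- function(params) {
  p <- .pvec(params)
  den <- p[7L] * (p[7L] + p[8L] + p[4L])
  if (den == 0) stop("division by zero: mu * (mu + phi1 + delta1) = 0",
                     call. = FALSE)
  p[2L] * p[1L] / den
}

#' Basic reproduction number of the smokers-only submodel
#'
#' Closed form `R0M = a2 * xi / (mu * (mu + phi2 + delta2))`.
#'
#' @param params model parameters.
#' @return Dimensionless scalar.
#' @export
r0_smokers <- function(params) {
  p <- .pvec(params)
  den <- p[7L] * (p[7L] + p[9L] + p[5L])
  if (den == 0) stop("division by zero: mu * (mu + phi2 + delta2) = 0",
                     call. = FALSE)
  p[3L] * p[1L] / den
}

#' Reproduction numbers via the next-generation matrix
#'
#' Builds the new-recruitment matrix F and transfer matrix V of the
#' infective subsystem (D, M, Dm) linearised at the habit-free equilibrium
#' S = xi / mu, forms F V^-1 and takes its spectral radius. The three
#' eigenvalues are the two submodel reproduction numbers and zero, so the
#' co-dependence reproduction number is `R0 = max(R0D, R0M)`; the numerical
#' spectrum is returned alongside the closed forms so the identity can be
#' checked to machine precision.
#'
#' @param params model parameters.
#' @return List of class `"codep_r0"` with elements `r0_codependence`,
#'   `r0_drinkers`, `r0_smokers`, `eigenvalues`, `F_matrix`, `V_matrix`.
#' @examples
#' reproduction_numbers(baseline_params())
#' @export
reproduction_numbers <- function(params) {
  p <- .pvec(validate_params(params))
  S0 <- p[1L] / p[7L]
  Fm <- rbind(c(p[2L] * S0, 0, p[2L] * S0),
              c(0, p[3L] * S0, p[3L] * S0),
              c(0, 0, 0))
  vdiag <- c(p[7L] + p[8L] + p[4L],
             p[7L] + p[9L] + p[5L],
             p[7L] + p[10L] + p[6L])
  if (any(vdiag == 0))
    stop("singular transfer matrix V: zero removal rate", call. = FALSE)
  Vm <- diag(vdiag)
  K <- Fm %*% solve(Vm)
  ev <- eigen(K, only.values = TRUE)$values
  structure(list(r0_codependence = max(Mod(ev)),
                 r0_drinkers = r0_drinkers(params),
                 r0_smokers = r0_smokers(params),
                 eigenvalues = ev,
                 F_matrix = Fm, V_matrix = Vm),
            class = "codep_r0")
}

#' @export
print.codep_r0 <- function(x, ...) {
  cat(sprintf("R0 (co-dependence) = %.6f  [drinkers %.6f, smokers %.6f]\n",
              x$r0_codependence, x$r0_drinkers, x$r0_smokers))
  invisible(x)
}

# Assemble an equilibrium report. `state` is the zero-padded 7-vector,
# `jac` the relevant Jacobian (3x3 for submodels, 7x7 for the full model),
# `r0` the threshold quantity the verdict is compared against.
.equilibrium_report <- function(label, state, params, jac, r0,
                                endemic = FALSE, marginal_tol = 1e-10) {
  names(state) <- .COMPARTMENTS
  resid <- max(abs(.rhs_unc(state, .pvec(params))))
  ev <- eigen(jac, only.values = TRUE)$values
  maxre <- max(Re(ev))
  verdict <- if (abs(maxre) < marginal_tol) "marginal"
             else if (maxre < 0) "stable" else "unstable"
  stable <- if (verdict == "marginal") NA else verdict == "stable"
  consistent <- if (verdict == "marginal") abs(r0 - 1) < 1e-8
                else if (endemic) stable == (r0 > 1) else stable == (r0 < 1)
  structure(list(label = label, state = state, residual = resid,
                 eigenvalues = ev, max_real_eigenvalue = maxre,
                 verdict = verdict, locally_stable = stable,
                 r0 = r0, r0_consistent = consistent),
            class = "codep_equilibrium")
}

#' @export
print.codep_equilibrium <- function(x, ...) {
  cat(sprintf("%s equilibrium (%s, R0 = %.5f)\n", x$label, x$verdict, x$r0))
  print(round(x$state, 6))
  cat(sprintf("residual %.3e, leading eigenvalue real part %.6g, R0-consistent: %s\n",
              x$residual, x$max_real_eigenvalue, x$r0_consistent))
  invisible(x)
}

# 3x3 Jacobian of the drinkers-only (or, mirrored, smokers-only) submodel
# at a (S, X, R) state with contact rate a, excess death f, recovery d,
# relapse g.
.sub_jacobian <- function(S, X, R, a, f, d, g, mu) {
  rbind(c(-(a * X + mu), -a * S, g),
        c(a * X, a * S - (mu + f + d), 0),
        c(0, d, -(mu + g)))
}

.sub_equilibria <- function(params, which = c("drinkers", "smokers"),
                            strict = FALSE) {
  which <- match.arg(which)
  p <- .pvec(validate_params(params))
  mu <- p[7L]; xi <- p[1L]
  if (which == "drinkers") {
    a <- p[2L]; f <- p[8L]; d <- p[4L]; g <- p[11L]
    slots <- c(1L, 2L, 5L)  # S, D, Rd
    labels <- c("DFE-drinkers", "EE-drinkers")
    r0 <- r0_drinkers(params)
  } else {
    a <- p[3L]; f <- p[9L]; d <- p[5L]; g <- p[12L]
    slots <- c(1L, 3L, 6L)  # S, M, Rm
    labels <- c("MFE-smokers", "EE-smokers")
    r0 <- r0_smokers(params)
  }
  pad <- function(S, X, R) {
    y <- numeric(7L); y[slots] <- c(S, X, R); y
  }
  # Habit-free equilibrium (xi/mu, 0, 0).
  free <- .equilibrium_report(labels[1L], pad(xi / mu, 0, 0), params,
                              .sub_jacobian(xi / mu, 0, 0, a, f, d, g, mu),
                              r0)
  # Endemic closed form: S* = (mu+f+d)/a; X* and R* from the steady-state
  # balance, admissible exactly when R0 > 1.
  ee <- NULL
  if (a > 0) {
    q <- mu + f + d
    den <- (mu + g) * q - g * d
    if (den != 0) {
      Sstar <- q / a
      Xstar <- (mu + g) * (xi * a - mu * q) / (a * den)
      Rstar <- d * Xstar / (mu + g)
      st <- pad(Sstar, Xstar, Rstar)
      if (any(st < 0)) {
        bad <- .COMPARTMENTS[which(st < 0)]
        msg <- sprintf("inadmissible endemic equilibrium (R0 = %.4f <= 1): negative component %s",
                       r0, paste(bad, collapse = ", "))
        if (strict) stop(msg, call. = FALSE)
        ee <- structure(list(label = labels[2L], state = st,
                             admissible = FALSE, r0 = r0, message = msg),
                        class = "codep_equilibrium")
      } else {
        ee <- .equilibrium_report(labels[2L], st, params,
                                  .sub_jacobian(Sstar, Xstar, Rstar, a, f,
                                                d, g, mu),
                                  r0, endemic = TRUE)
        ee$admissible <- TRUE
      }
    }
  }
  list(free = free, endemic = ee)
}

#' Equilibria of the drinkers-only submodel
#'
#' Returns the drinking-free equilibrium `(xi/mu, 0, 0)` and the closed-form
#' endemic equilibrium of the S-D-Rd submodel, each zero-padded to the full
#' seven compartments, with right-hand-side residual, submodel Jacobian
#' spectrum and stability verdict. The endemic state is admissible exactly
#' when `R0D > 1`; with `strict = TRUE` an inadmissible endemic state is an
#' error naming the negative component, otherwise it is returned flagged
#' `admissible = FALSE`.
#'
#' @param params model parameters.
#' @param strict error on an inadmissible endemic equilibrium.
#' @return List with elements `free` and `endemic` (class
#'   `"codep_equilibrium"`).
#' @export
drinker_equilibria <- function(params, strict = FALSE) {
  .sub_equilibria(params, "drinkers", strict)
}

#' Equilibria of the smokers-only submodel
#'
#' Mirror of [drinker_equilibria()] for the S-M-Rm submodel with rates
#' `(a2, phi2, delta2, gamma2)`; admissible endemic state requires
#' `R0M > 1`.
#'
#' @inheritParams drinker_equilibria
#' @return List with elements `free` and `endemic`.
#' @export
smoker_equilibria <- function(params, strict = FALSE) {
  .sub_equilibria(params, "smokers", strict)
}

#' Jacobian of the uncontrolled dynamics
#'
#' Exact analytic 7x7 Jacobian of the uncontrolled right-hand side at an
#' arbitrary state. The right-hand side is polynomial (the forces of
#' co-dependence are bilinear in the state), so every entry is an exact
#' partial derivative.
#'
#' @param state compartment state vector.
#' @param params model parameters.
#' @return 7x7 numeric matrix, rows and columns in compartment order.
#' @export
model_jacobian <- function(state, params) {
  y <- .svec(state)
  p <- .pvec(params)
  S <- y[1L]; D <- y[2L]; M <- y[3L]; Dm <- y[4L]
  a1 <- p[2L]; a2 <- p[3L]; mu <- p[7L]
  al1 <- a1 * (D + Dm)
  al2 <- a2 * (M + Dm)
  J <- matrix(0, 7L, 7L, dimnames = list(.COMPARTMENTS, .COMPARTMENTS))
  J[1L, ] <- c(-(al1 + al2 + mu), -a1 * S, -a2 * S, -(a1 + a2) * S,
               p[11L], p[12L], p[13L])
  J[2L, 1L:4L] <- c(al1, a1 * S - (mu + p[8L] + p[4L] + al2), -a2 * D,
                    a1 * S - a2 * D)
  J[3L, 1L:4L] <- c(al2, -a1 * M, a2 * S - (mu + p[9L] + p[5L] + al1),
                    a2 * S - a1 * M)
  J[4L, 2L:4L] <- c(al2 + a1 * M, a2 * D + al1,
                    a2 * D + a1 * M - (mu + p[10L] + p[6L]))
  J[5L, c(2L, 5L)] <- c(p[4L], -(mu + p[11L]))
  J[6L, c(3L, 6L)] <- c(p[5L], -(mu + p[12L]))
  J[7L, c(4L, 7L)] <- c(p[6L], -(mu + p[13L]))
  J
}

#' Stability verdict at the habit-free equilibrium of the full model
#'
#' Computes the drinking-and-smoking-free equilibrium `(xi/mu, 0, ..., 0)`,
#' the full 7x7 Jacobian spectrum there, and reports whether the eigenvalue
#' verdict agrees with the threshold criterion `max(R0D, R0M) < 1`. A
#' leading eigenvalue whose real part lies within 1e-10 of zero yields the
#' verdict `"marginal"` (neither stable nor unstable).
#'
#' @param params model parameters.
#' @return A `"codep_equilibrium"` report labelled `"DMFE-full"`, with the
#'   submodel reproduction numbers attached.
#' @examples
#' stability_report(baseline_params())
#' @export
stability_report <- function(params) {
  p <- .pvec(validate_params(params))
  dmfe <- c(p[1L] / p[7L], rep(0, 6L))
  r0d <- r0_drinkers(params)
  r0m <- r0_smokers(params)
  rep_ <- .equilibrium_report("DMFE-full", dmfe, params,
                              model_jacobian(dmfe, params), max(r0d, r0m))
  rep_$r0_drinkers <- r0d
  rep_$r0_smokers <- r0m
  rep_
}

#' Endemic equilibrium of the full model, located numerically
#'
#' The full seven-compartment model has no closed-form endemic state; this
#' locates one by integrating the dynamics over a long horizon and
#' polishing the endpoint with damped Newton iteration on the right-hand
#' side using the analytic Jacobian. The report carries the same residual
#' contract as the closed-form equilibria.
#'
#' @param params model parameters.
#' @param state0 starting state for the long run.
#' @param horizon length of the preliminary run (weeks).
#' @param step integration step for the preliminary run (weeks).
#' @param tol Newton residual target (max-norm).
#' @param max_iter Newton iteration cap.
#' @return A `"codep_equilibrium"` report labelled `"EE-full"`.
#' @export
endemic_equilibrium <- function(params, state0 = initial_state(),
                                horizon = 2000, step = 0.05, tol = 1e-12,
                                max_iter = 100) {
  p <- .pvec(validate_params(params))
  y <- .integrate_mat(matrix(.svec(state0), 1L), p, 0, horizon, step)[1L, ]
  f <- .rhs_unc(y, p)
  for (it in seq_len(max_iter)) {
    if (max(abs(f)) <= tol) break
    dy <- solve(model_jacobian(y, params), -f)
    lam <- 1
    repeat {
      ynew <- y + lam * dy
      fnew <- .rhs_unc(ynew, p)
      if (max(abs(fnew)) < max(abs(f)) || lam < 1e-8) break
      lam <- lam / 2
    }
    y <- ynew; f <- fnew
  }
  r0 <- max(r0_drinkers(params), r0_smokers(params))
  .equilibrium_report("EE-full", y, params, model_jacobian(y, params), r0,
                      endemic = TRUE)
}

#' Numerical probe of global attraction to the habit-free state
#'
#' Integrates a batch of random admissible initial states over a long
#' horizon and reports the max-norm distance of each endpoint from the
#' habit-free equilibrium. Used as the numerical surrogate for the global
#' stability of that state when `max(R0D, R0M) < 1`.
#'
#' @param params model parameters.
#' @param n_states number of random initial states.
#' @param horizon integration horizon (weeks).
#' @param step integration step (weeks).
#' @param seed RNG seed for the initial states.
#' @param scale upper bound of the uniform draw for each compartment.
#' @return Numeric vector of final distances, one per initial state.
#' @export
attraction_probe <- function(params, n_states = 20, horizon = 2000,
                             step = 0.05, seed = 1, scale = 1) {
  p <- .pvec(validate_params(params))
  set.seed(seed)
  Y0 <- matrix(stats::runif(n_states * 7L, 0, scale), n_states, 7L)
  Yend <- .integrate_mat(Y0, p, 0, horizon, step)
  dmfe <- c(p[1L] / p[7L], rep(0, 6L))
  apply(abs(sweep(Yend, 2L, dmfe)), 1L, max)
}
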
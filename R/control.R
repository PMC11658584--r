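#' Objective weights for the optimal-control problem
#'
#' State-cost weights `A1, A2, A3` on the drinkers, smokers and
#' co-dependent compartments and quadratic control-cost weights
#' `w1, ..., w5`. All must be positive. The defaults are the package's
#' reference scenario (A = 100, w = 0.5).
#'
#' @param A1,A2,A3 state-cost weights.
#' @param w1,w2,w3,w4,w5 control-cost weights.
#' @return Named numeric vector of class `"codep_weights"`.
#' @export
objective_weights <- function(A1 = 100, A2 = 100, A3 = 100, w1 = 0.5,
                              w2 = 0.5, w3 = 0.5, w4 = 0.5, w5 = 0.5) {
  w <- c(A1 = A1, A2 = A2, A3 = A3, w1 = w1, w2 = w2, w3 = w3, w4 = w4,
         w5 = w5)
  if (anyNA(w) || any(!is.finite(w)) || any(w <= 0))
    stop("all objective weights must be positive and finite", call. = FALSE)
  structure(w, class = "codep_weights")
}

.wvec <- function(w) as.numeric(w[c("A1", "A2", "A3", "w1", "w2", "w3",
                                    "w4", "w5")])

.check_controls <- function(u) {
  if (length(u) != 5L) stop("need 5 control values", call. = FALSE)
  if (anyNA(u) || any(u < 0) || any(u > 1))
    stop("control out of bounds: each u must lie in [0, 1]", call. = FALSE)
  as.numeric(u)
}

# Controlled right-hand side; u length 5, bare double state/params.
# u1, u2 scale down the two recruitment flows; u3, u4, u5 add recovery
# out of Dm, D, M respectively.
.rhs_ctrl <- function(y, u, p) {
  S <- y[1L]; D <- y[2L]; M <- y[3L]; Dm <- y[4L]
  mu <- p[7L]
  i1 <- (1 - u[1L]) * p[2L] * (D + Dm)
  i2 <- (1 - u[2L]) * p[3L] * (M + Dm)
  c(p[1L] + p[11L] * y[5L] + p[12L] * y[6L] + p[13L] * y[7L] -
      (i1 + i2 + mu) * S,
    i1 * S - (mu + p[8L] + p[4L] + u[4L]) * D - i2 * D,
    i2 * S - (mu + p[9L] + p[5L] + u[5L] + i1) * M,
    i2 * D + i1 * M - (mu + p[10L] + p[6L] + u[3L]) * Dm,
    (p[4L] + u[4L]) * D - (mu + p[11L]) * y[5L],
    (p[5L] + u[5L]) * M - (mu + p[12L]) * y[6L],
    (p[6L] + u[3L]) * Dm - (mu + p[13L]) * y[7L])
}

#' Controlled model right-hand side
#'
#' Dynamics under the five bounded controls: `u1` (drinking prevention)
#' and `u2` (smoking prevention) scale the respective recruitment flows by
#' `(1 - u)`; `u3`, `u4`, `u5` add recovery effort out of the co-dependent,
#' drinker and smoker compartments. With all controls zero this reduces
#' exactly to [model_rhs()].
#'
#' @param t time in weeks (unused; the controlled system is autonomous for
#'   fixed control values).
#' @param state compartment state vector.
#' @param controls numeric vector `(u1, ..., u5)`, each in [0, 1].
#' @param params model parameters.
#' @return Named derivative vector.
#' @export
controlled_rhs <- function(t, state, controls, params) {
  u <- .check_controls(controls)
  dy <- .rhs_ctrl(.svec(state), u, .pvec(params))
  names(dy) <- .COMPARTMENTS
  dy
}

#' Control objective functional
#'
#' The running cost `A1*D + A2*M + A3*Dm + sum_k (w_k/2) u_k^2` integrated
#' over the trajectory's time grid by the composite trapezoidal rule.
#'
#' @param trajectory a `"codep_trajectory"` (or list with `times`,
#'   `states`).
#' @param controls matrix of control values, one row per grid point, five
#'   columns; or `NULL` for the uncontrolled cost.
#' @param weights objective weights (see [objective_weights()]).
#' @return Scalar value of the objective J.
#' @export
control_objective <- function(trajectory, controls, weights) {
  w <- .wvec(weights)
  times <- trajectory$times
  st <- trajectory$states
  if (is.null(controls)) controls <- matrix(0, length(times), 5L)
  controls <- as.matrix(controls)
  if (nrow(controls) != length(times))
    stop("grid mismatch: controls and trajectory must share the time grid",
         call. = FALSE)
  integrand <- w[1L] * st[, 2L] + w[2L] * st[, 3L] + w[3L] * st[, 4L] +
    0.5 * (controls^2 %*% w[4L:8L])[, 1L]
  .trapz(times, integrand)
}

.trapz <- function(x, y) {
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Hamiltonian on bare doubles.
.hamiltonian <- function(y, u, lam, p, w) {
  w[1L] * y[2L] + w[2L] * y[3L] + w[3L] * y[4L] +
    0.5 * sum(w[4L:8L] * u^2) + sum(lam * .rhs_ctrl(y, u, p))
}

#' Pontryagin Hamiltonian
#'
#' Running cost plus the co-state-weighted controlled dynamics:
#' `H = A1*D + A2*M + A3*Dm + sum_k (w_k/2) u_k^2 + sum_i lambda_i f_i`,
#' where `f` is the controlled right-hand side. H is quadratic in each
#' control and (because the recruitment forces are bilinear in the state)
#' quadratic in the state as well.
#'
#' @param state compartment state vector.
#' @param controls five control values in [0, 1].
#' @param adjoints co-state vector `lambda1..lambda7` in compartment order.
#' @param params model parameters.
#' @param weights objective weights.
#' @return Scalar Hamiltonian value.
#' @export
hamiltonian <- function(state, controls, adjoints, params, weights) {
  .hamiltonian(.svec(state), .check_controls(controls),
               as.numeric(adjoints), .pvec(params), .wvec(weights))
}

# Adjoint right-hand side dlambda/dt = -dH/dstate, derived from the
# implemented Hamiltonian with the recruitment forces alpha1 = a1(D+Dm),
# alpha2 = a2(M+Dm) treated as state functions (their D, M, Dm
# derivatives contribute the a1*S, a1*M, a2*S, a2*D terms below).
.adj_rhs <- function(y, u, lam, p, w) {
  S <- y[1L]; D <- y[2L]; M <- y[3L]; Dm <- y[4L]
  mu <- p[7L]; a1 <- p[2L]; a2 <- p[3L]
  b1 <- 1 - u[1L]; b2 <- 1 - u[2L]
  al1 <- a1 * (D + Dm)
  al2 <- a2 * (M + Dm)
  l1 <- lam[1L]; l2 <- lam[2L]; l3 <- lam[3L]; l4 <- lam[4L]
  l5 <- lam[5L]; l6 <- lam[6L]; l7 <- lam[7L]
  rD <- mu + p[8L] + p[4L] + u[4L]    # removal from D
  rM <- mu + p[9L] + p[5L] + u[5L]    # removal from M
  rDm <- mu + p[10L] + p[6L] + u[3L]  # removal from Dm
  c(l1 * (b1 * al1 + b2 * al2 + mu) - l2 * b1 * al1 - l3 * b2 * al2,
    -w[1L] + l1 * b1 * a1 * S -
      l2 * (b1 * a1 * S - rD - b2 * al2) + l3 * b1 * a1 * M -
      l4 * (b2 * al2 + b1 * a1 * M) - l5 * (p[4L] + u[4L]),
    -w[2L] + l1 * b2 * a2 * S + l2 * b2 * a2 * D -
      l3 * (b2 * a2 * S - rM - b1 * al1) -
      l4 * (b2 * a2 * D + b1 * al1) - l6 * (p[5L] + u[5L]),
    -w[3L] + l1 * (b1 * a1 * S + b2 * a2 * S) -
      l2 * (b1 * a1 * S - b2 * a2 * D) - l3 * (b2 * a2 * S - b1 * a1 * M) -
      l4 * (b2 * a2 * D + b1 * a1 * M - rDm) - l7 * (p[6L] + u[3L]),
    l5 * (mu + p[11L]) - l1 * p[11L],
    l6 * (mu + p[12L]) - l1 * p[12L],
    l7 * (mu + p[13L]) - l1 * p[13L])
}

#' Adjoint (co-state) right-hand side
#'
#' The seven co-state derivatives `dlambda_i/dt = -dH/dstate_i`, obtained
#' by differentiating the implemented Hamiltonian analytically, including
#' the dependence of the recruitment forces on D, M and Dm. The terminal
#' condition of the control problem is `lambda(T) = 0` (transversality).
#'
#' @inheritParams hamiltonian
#' @return Named numeric vector `lambda1..lambda7` derivatives.
#' @export
adjoint_rhs <- function(state, controls, adjoints, params, weights) {
  dl <- .adj_rhs(.svec(state), .check_controls(controls),
                 as.numeric(adjoints), .pvec(params), .wvec(weights))
  names(dl) <- paste0("lambda", 1:7)
  dl
}

# Stationary control values Phi_k = argmin_u H, before clamping.
# Vectorised: Y and L may be matrices (one grid point per row).
.phi <- function(Y, L, p, w) {
  S <- Y[, 1L]; D <- Y[, 2L]; M <- Y[, 3L]; Dm <- Y[, 4L]
  al1 <- p[2L] * (D + Dm)
  al2 <- p[3L] * (M + Dm)
  cbind(((L[, 2L] - L[, 1L]) * al1 * S + (L[, 4L] - L[, 3L]) * al1 * M) /
          w[4L],
        ((L[, 3L] - L[, 1L]) * al2 * S + (L[, 4L] - L[, 2L]) * al2 * D) /
          w[5L],
        (L[, 4L] - L[, 7L]) * Dm / w[6L],
        (L[, 2L] - L[, 5L]) * D / w[7L],
        (L[, 3L] - L[, 6L]) * M / w[8L])
}

#' Characterized (stationary) controls with clamping
#'
#' Evaluates the stationarity condition `dH/du_k = 0` of the quadratic
#' Hamiltonian in each control and clamps the result to the control
#' bounds. An interior returned value is an exact stationary point of H in
#' that control.
#'
#' @param state compartment state vector.
#' @param adjoints co-state vector.
#' @param params model parameters.
#' @param weights objective weights.
#' @param bounds 2 x 5 matrix (or list of `c(lower, upper)`) of per-control
#'   bounds inside [0, 1]; default the full box.
#' @return Named vector `(u1, ..., u5)`.
#' @export
update_controls <- function(state, adjoints, params, weights,
                            bounds = control_bounds()) {
  b <- .bounds_matrix(bounds)
  w <- .wvec(weights)
  if (any(w[4L:8L] == 0)) stop("zero control-cost weight", call. = FALSE)
  phi <- .phi(matrix(.svec(state), 1L), matrix(as.numeric(adjoints), 1L),
              .pvec(params), w)[1L, ]
  u <- pmin(pmax(phi, b[1L, ]), b[2L, ])
  names(u) <- paste0("u", 1:5)
  u
}

#' Control bounds
#'
#' Per-control lower and upper bounds inside the unit box. Disabling a
#' control amounts to setting its bounds to `(0, 0)`.
#'
#' @param lower,upper numeric length 1 or 5.
#' @param enabled logical length 5 (or integer subset of 1:5); disabled
#'   controls get bounds `(0, 0)`.
#' @return A 2 x 5 matrix with rows `lower`, `upper`.
#' @export
control_bounds <- function(lower = 0, upper = 1, enabled = 1:5) {
  b <- rbind(lower = rep_len(lower, 5L), upper = rep_len(upper, 5L))
  colnames(b) <- paste0("u", 1:5)
  if (is.logical(enabled)) enabled <- which(enabled)
  disabled <- setdiff(1:5, enabled)
  b[, disabled] <- 0
  .bounds_matrix(b)
}

.bounds_matrix <- function(bounds) {
  if (is.list(bounds)) bounds <- vapply(bounds, as.numeric, numeric(2L))
  b <- matrix(as.numeric(bounds), 2L, 5L)
  if (any(b < 0) || any(b > 1) || any(b[1L, ] > b[2L, ]))
    stop("control bounds must satisfy 0 <= lower <= upper <= 1",
         call. = FALSE)
  rownames(b) <- c("lower", "upper")
  colnames(b) <- paste0("u", 1:5)
  b
}

# Forward RK4 pass with piecewise-linear controls (midpoint = average of
# the two grid nodes). Returns the n x 7 state matrix.
.sweep_forward <- function(y0, U, p, times) {
  n <- length(times)
  Y <- matrix(NA_real_, n, 7L)
  y <- y0
  Y[1L, ] <- y
  for (i in seq_len(n - 1L)) {
    h <- times[i + 1L] - times[i]
    ui <- U[i, ]; uj <- U[i + 1L, ]; um <- 0.5 * (ui + uj)
    k1 <- .rhs_ctrl(y, ui, p)
    k2 <- .rhs_ctrl(y + (h / 2) * k1, um, p)
    k3 <- .rhs_ctrl(y + (h / 2) * k2, um, p)
    k4 <- .rhs_ctrl(y + h * k3, uj, p)
    y <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    Y[i + 1L, ] <- y
  }
  if (max(abs(Y)) > 1e12)
    stop("integration blow-up: state magnitude exceeded 1e12",
         call. = FALSE)
  Y
}

# Backward RK4 pass for the adjoints from lambda(T) = 0; the stored
# forward states are interpolated linearly at the half-steps.
.sweep_backward <- function(Y, U, p, w, times) {
  n <- length(times)
  L <- matrix(NA_real_, n, 7L)
  l <- numeric(7L)
  L[n, ] <- l
  for (i in (n - 1L):1L) {
    h <- times[i + 1L] - times[i]
    yi <- Y[i, ]; yj <- Y[i + 1L, ]; ym <- 0.5 * (yi + yj)
    ui <- U[i, ]; uj <- U[i + 1L, ]; um <- 0.5 * (ui + uj)
    k1 <- .adj_rhs(yj, uj, l, p, w)
    k2 <- .adj_rhs(ym, um, l - (h / 2) * k1, p, w)
    k3 <- .adj_rhs(ym, um, l - (h / 2) * k2, p, w)
    k4 <- .adj_rhs(yi, ui, l - h * k3, p, w)
    l <- l - (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    L[i, ] <- l
  }
  L
}

#' Solve the optimal-control problem by forward-backward sweep
#'
#' Iterates (i) forward RK4 integration of the controlled dynamics under
#' the current control path, (ii) backward RK4 integration of the adjoint
#' system from the transversality condition `lambda(T) = 0`, and (iii) a
#' relaxed update of the controls toward their clamped stationary values,
#' `u_new = relaxation * clamp(Phi) + (1 - relaxation) * u_old`. The sweep
#' stops when, for every control, the L1 change satisfies
#' `||u_new - u_old|| <= tol * ||u_new||` (absolute comparison against
#' `tol` when `||u_new|| = 0`), or at `max_iter`; non-convergence is
#' reported in the solution, not raised.
#'
#' @param params model parameters.
#' @param state0 initial state.
#' @param weights objective weights.
#' @param horizon control horizon T (weeks).
#' @param step grid step (weeks).
#' @param bounds per-control bounds (see [control_bounds()]).
#' @param tol relative L1 convergence tolerance per control.
#' @param max_iter iteration cap.
#' @param relaxation update blending factor in (0, 1].
#' @param u_init initial control path: scalar, length-5 vector or
#'   n x 5 matrix.
#' @return Object of class `"codep_oc"`: `times`, `states`, `adjoints`,
#'   `controls`, `objective`, `objective_uncontrolled`, `baseline` (the
#'   uncontrolled trajectory on the same grid), `iterations`, `converged`
#'   and the per-iteration `log`.
#' @examples
#' sol <- optimal_control(baseline_params(), horizon = 2, step = 0.05)
#' sol$objective < sol$objective_uncontrolled
#' @export
optimal_control <- function(params, state0 = initial_state(),
                            weights = objective_weights(), horizon = 52,
                            step = 0.01, bounds = control_bounds(),
                            tol = 1e-3, max_iter = 200, relaxation = 0.5,
                            u_init = 0) {
  if (!(tol > 0)) stop("tol must be positive", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be >= 1", call. = FALSE)
  if (!(relaxation > 0 && relaxation <= 1))
    stop("relaxation must lie in (0, 1]", call. = FALSE)
  p <- .pvec(validate_params(params))
  w <- .wvec(weights)
  b <- .bounds_matrix(bounds)
  y0 <- .svec(state0)
  times <- .time_grid(0, horizon, step)
  n <- length(times)
  U <- if (is.matrix(u_init)) u_init else
    matrix(rep_len(as.numeric(u_init), 5L), n, 5L, byrow = TRUE)
  U <- pmin(pmax(U, matrix(b[1L, ], n, 5L, byrow = TRUE)),
            matrix(b[2L, ], n, 5L, byrow = TRUE))
  lo <- matrix(b[1L, ], n, 5L, byrow = TRUE)
  hi <- matrix(b[2L, ], n, 5L, byrow = TRUE)
  iter_log <- data.frame(iteration = integer(), objective = numeric(),
                    max_rel_change = numeric())
  converged <- FALSE
  Y <- NULL; L <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Y <- .sweep_forward(y0, U, p, times)
    L <- .sweep_backward(Y, U, p, w, times)
    Uchar <- pmin(pmax(.phi(Y, L, p, w), lo), hi)
    Unew <- relaxation * Uchar + (1 - relaxation) * U
    num <- colSums(abs(Unew - U))
    den <- colSums(abs(Unew))
    rel <- ifelse(den > 0, num / den, num)
    J <- control_objective(list(times = times, states = Y), U, weights)
    iter_log <- rbind(iter_log,
                      data.frame(iteration = iter, objective = J,
                                 max_rel_change = max(rel)))
    U <- Unew
    if (all(num <= ifelse(den > 0, tol * den, tol))) {
      converged <- TRUE
      break
    }
  }
  # Final forward pass so states, adjoints and objective match the
  # returned control path.
  Y <- .sweep_forward(y0, U, p, times)
  L <- .sweep_backward(Y, U, p, w, times)
  colnames(Y) <- .COMPARTMENTS
  colnames(L) <- paste0("lambda", 1:7)
  colnames(U) <- paste0("u", 1:5)
  J <- control_objective(list(times = times, states = Y), U, weights)
  base <- rk4_integrate(function(t, y) .rhs_unc(y, p), y0, 0, horizon,
                        step)
  colnames(base$states) <- .COMPARTMENTS
  J0 <- control_objective(base, NULL, weights)
  structure(list(times = times, states = Y, adjoints = L, controls = U,
                 objective = J, objective_uncontrolled = J0,
                 baseline = base, iterations = iter, converged = converged,
                 log = iter_log, params = params, weights = weights,
                 bounds = b, tol = tol, relaxation = relaxation),
            class = "codep_oc")
}

#' @export
print.codep_oc <- function(x, ...) {
  cat(sprintf("Optimal-control solution (%s after %d sweep iterations)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat(sprintf("  J = %.6f (uncontrolled J = %.6f)\n", x$objective,
              x$objective_uncontrolled))
  invisible(x)
}

#' @export
summary.codep_oc <- function(object, ...) {
  u <- object$controls
  cat(sprintf("Forward-backward sweep: %d iterations, converged = %s\n",
              object$iterations, object$converged))
  cat(sprintf("Objective: %.6f with control, %.6f without (reduction %.1f%%)\n",
              object$objective, object$objective_uncontrolled,
              100 * (1 - object$objective / object$objective_uncontrolled)))
  cat("Control ranges over the horizon:\n")
  print(round(apply(u, 2L, range), 4))
  invisible(object)
}

#' @param x solution object.
#' @param what `"states"` or `"controls"`.
#' @param ... passed to [graphics::matplot()].
#' @rdname optimal_control
#' @export
plot.codep_oc <- function(x, what = c("states", "controls"), ...) {
  what <- match.arg(what)
  if (what == "states") {
    graphics::matplot(x$times, x$states, type = "l", lty = 1, col = 1:7,
                      xlab = "time (weeks)", ylab = "compartment size",
                      ...)
    graphics::legend("topright", legend = colnames(x$states), col = 1:7,
                     lty = 1, bty = "n")
  } else {
    graphics::matplot(x$times, x$controls, type = "l", lty = 1, col = 1:5,
                      ylim = c(0, 1), xlab = "time (weeks)",
                      ylab = "control level", ...)
    graphics::legend("topright", legend = colnames(x$controls), col = 1:5,
                     lty = 1, bty = "n")
  }
  invisible(x)
}

#' Control efficacy trajectory
#'
#' Fractional reduction of a compartment attributable to the controls,
#' `E(t) = 1 - X_controlled(t) / X_baseline(t)` per grid point. Grid points
#' where the baseline compartment is zero are undefined and reported as
#' `NA`.
#'
#' @param controlled trajectory (or `"codep_oc"` solution) under control.
#' @param baseline uncontrolled trajectory on the same grid; defaults to
#'   the baseline stored in a `"codep_oc"` solution.
#' @param compartment one of `"D"`, `"M"`, `"Dm"`.
#' @return Numeric vector of efficacies, one per grid point.
#' @export
control_efficacy <- function(controlled, baseline = NULL,
                             compartment = c("D", "M", "Dm")) {
  compartment <- match.arg(compartment)
  if (inherits(controlled, "codep_oc")) {
    if (is.null(baseline)) baseline <- controlled$baseline
    controlled <- list(times = controlled$times,
                       states = controlled$states)
  }
  if (is.null(baseline))
    stop("a baseline trajectory is required", call. = FALSE)
  if (length(controlled$times) != length(baseline$times) ||
      max(abs(controlled$times - baseline$times)) > 1e-12)
    stop("grid mismatch between controlled and baseline trajectories",
         call. = FALSE)
  j <- match(compartment, .COMPARTMENTS)
  xc <- controlled$states[, j]
  xb <- baseline$states[, j]
  e <- 1 - xc / xb
  e[xb == 0] <- NA_real_
  e
}

#' First-order optimality probe of a converged solution
#'
#' Perturbs the converged control path by `+/- delta` in one control over
#' one subinterval at a time (clamped to the bounds), re-integrates the
#' dynamics, and records the resulting change in the objective. At a
#' discrete optimum no such perturbation should lower J by more than the
#' discretisation noise.
#'
#' @param solution a `"codep_oc"` object.
#' @param delta perturbation size.
#' @param n_intervals number of equal subintervals of the horizon to
#'   perturb.
#' @return Data frame with columns `control`, `interval`, `direction`,
#'   `delta_J` (objective change; negative means the perturbation improved
#'   on the returned solution).
#' @export
check_local_optimality <- function(solution, delta = 0.01,
                                   n_intervals = 10) {
  p <- .pvec(solution$params)
  w <- solution$weights
  b <- solution$bounds
  times <- solution$times
  y0 <- solution$states[1L, ]
  n <- length(times)
  breaks <- seq(times[1L], times[n], length.out = n_intervals + 1L)
  out <- expand.grid(control = 1:5, interval = seq_len(n_intervals),
                     direction = c(1, -1))
  out$delta_J <- NA_real_
  for (r in seq_len(nrow(out))) {
    k <- out$control[r]
    iv <- out$interval[r]
    idx <- times >= breaks[iv] & times <= breaks[iv + 1L]
    U <- solution$controls
    U[idx, k] <- pmin(pmax(U[idx, k] + out$direction[r] * delta,
                           b[1L, k]), b[2L, k])
    Y <- .sweep_forward(y0, U, p, times)
    out$delta_J[r] <- control_objective(list(times = times, states = Y),
                                        U, w) - solution$objective
  }
  out
}
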
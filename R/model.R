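#' Forces of co-dependence
#'
#' State-dependent per-capita recruitment rates into drinking and smoking:
#' `alpha1 = a1 * (D + Dm)` and `alpha2 = a2 * (M + Dm)`. Drinkers and
#' co-dependent individuals recruit new drinkers; smokers and co-dependent
#' individuals recruit new smokers.
#'
#' @param state compartment state vector (see [model_state()]).
#' @param params model parameters (see [model_params()]).
#' @return Named numeric `c(alpha1, alpha2)`, both per week.
#' @export
codependence_force <- function(state, params) {
  y <- .svec(state)
  p <- .pvec(params)
  c(alpha1 = p[2L] * (y[2L] + y[4L]), alpha2 = p[3L] * (y[3L] + y[4L]))
}

# Uncontrolled right-hand side on a bare double state. Index map:
# p = (xi, a1, a2, delta1, delta2, k1, mu, phi1, phi2, phi3, g1, g2, g3)
# y = (S, D, M, Dm, Rd, Rm, Rdm)
.rhs_unc <- function(y, p) {
  S <- y[1L]; D <- y[2L]; M <- y[3L]; Dm <- y[4L]
  al1 <- p[2L] * (D + Dm)
  al2 <- p[3L] * (M + Dm)
  mu <- p[7L]
  c(p[1L] + p[11L] * y[5L] + p[12L] * y[6L] + p[13L] * y[7L] -
      (al1 + al2 + mu) * S,
    al1 * S - (mu + p[8L] + p[4L] + al2) * D,
    al2 * S - (mu + p[9L] + p[5L] + al1) * M,
    al2 * D + al1 * M - (mu + p[10L] + p[6L]) * Dm,
    p[4L] * D - (mu + p[11L]) * y[5L],
    p[5L] * M - (mu + p[12L]) * y[6L],
    p[6L] * Dm - (mu + p[13L]) * y[7L])
}

# Vectorised variant: Y is n x 7; P is either a length-13 vector shared by
# all rows or an n x 13 matrix (one parameter set per row). Used by the
# stability probes and the trajectory-output global sensitivity, where many
# trajectories advance in lock-step.
.rhs_unc_mat <- function(Y, P) {
  if (is.matrix(P)) {
    xi <- P[, 1L]; a1 <- P[, 2L]; a2 <- P[, 3L]; d1 <- P[, 4L]
    d2 <- P[, 5L]; k1 <- P[, 6L]; mu <- P[, 7L]; f1 <- P[, 8L]
    f2 <- P[, 9L]; f3 <- P[, 10L]; g1 <- P[, 11L]; g2 <- P[, 12L]
    g3 <- P[, 13L]
  } else {
    xi <- P[1L]; a1 <- P[2L]; a2 <- P[3L]; d1 <- P[4L]; d2 <- P[5L]
    k1 <- P[6L]; mu <- P[7L]; f1 <- P[8L]; f2 <- P[9L]; f3 <- P[10L]
    g1 <- P[11L]; g2 <- P[12L]; g3 <- P[13L]
  }
  S <- Y[, 1L]; D <- Y[, 2L]; M <- Y[, 3L]; Dm <- Y[, 4L]
  al1 <- a1 * (D + Dm)
  al2 <- a2 * (M + Dm)
  cbind(xi + g1 * Y[, 5L] + g2 * Y[, 6L] + g3 * Y[, 7L] -
          (al1 + al2 + mu) * S,
        al1 * S - (mu + f1 + d1 + al2) * D,
        al2 * S - (mu + f2 + d2 + al1) * M,
        al2 * D + al1 * M - (mu + f3 + k1) * Dm,
        d1 * D - (mu + g1) * Y[, 5L],
        d2 * M - (mu + g2) * Y[, 6L],
        k1 * Dm - (mu + g3) * Y[, 7L])
}

#' Uncontrolled model right-hand side
#'
#' Time derivative of the seven compartments under the uncontrolled
#' dynamics. The system is autonomous; `t` is accepted for integrator
#' compatibility and ignored. The forces of co-dependence are recomputed
#' from the supplied state, so the derivative is exact at any point, not a
#' per-step linearisation.
#'
#' @param t time in weeks (unused).
#' @param state compartment state vector.
#' @param params model parameters.
#' @return Named numeric vector of the seven derivatives.
#' @export
model_rhs <- function(t, state, params) {
  p <- .pvec(params)
  if (any(p < 0)) stop("negative parameters", call. = FALSE)
  dy <- .rhs_unc(.svec(state), p)
  names(dy) <- .COMPARTMENTS
  dy
}

#' Fixed-step classical Runge-Kutta integration
#'
#' Integrates `dy/dt = rhs(t, y)` with the classical four-stage
#' fourth-order scheme on a uniform grid from `t0` to `t1`. If `step` does
#' not divide the interval to within one part in 1e9, the final step is
#' shortened so the trajectory still ends exactly at `t1`. Both endpoints
#' are included in the output. States are never clipped; if any component
#' magnitude exceeds 1e12 the integration aborts with an error, since that
#' signals a diverging solution rather than admissible dynamics.
#'
#' @param rhs function `(t, y)` returning the derivative of `y`.
#' @param state0 initial state (any length; named vectors keep their names).
#' @param t0,t1 integration window, `t1 > t0` (weeks).
#' @param step positive step size (weeks).
#' @return Object of class `"codep_trajectory"`: list with `times` and a
#'   row-per-time `states` matrix.
#' @examples
#' tr <- rk4_integrate(function(t, y) -0.1 * y, c(x = 1), 0, 10, 0.01)
#' utils::tail(as.data.frame(tr), 1)
#' @export
rk4_integrate <- function(rhs, state0, t0, t1, step) {
  if (!(t1 > t0)) stop("t1 must exceed t0", call. = FALSE)
  if (!(step > 0)) stop("step must be positive", call. = FALSE)
  times <- .time_grid(t0, t1, step)
  n <- length(times)
  y <- as.numeric(state0)
  Y <- matrix(NA_real_, n, length(y))
  colnames(Y) <- names(state0)
  Y[1L, ] <- y
  for (i in seq_len(n - 1L)) {
    h <- times[i + 1L] - times[i]
    tm <- times[i]
    k1 <- rhs(tm, y)
    k2 <- rhs(tm + h / 2, y + (h / 2) * k1)
    k3 <- rhs(tm + h / 2, y + (h / 2) * k2)
    k4 <- rhs(tm + h, y + h * k3)
    y <- y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (max(abs(y)) > 1e12)
      stop("integration blow-up: state magnitude exceeded 1e12",
           call. = FALSE)
    Y[i + 1L, ] <- y
  }
  structure(list(times = times, states = Y), class = "codep_trajectory")
}

.time_grid <- function(t0, t1, step) {
  span <- t1 - t0
  m <- span / step
  if (abs(m - round(m)) < 1e-9 * max(1, abs(m))) {
    times <- t0 + step * seq.int(0L, round(m))
  } else {
    times <- c(t0 + step * seq.int(0L, floor(m)), t1)
  }
  times[length(times)] <- t1
  times
}

#' Simulate the uncontrolled model
#'
#' Integrates the uncontrolled dynamics from `state0` over `horizon` weeks
#' with [rk4_integrate()]. The default step of 0.01 weeks makes the
#' discretisation error of the fourth-order scheme negligible against all
#' tolerances used in the package.
#'
#' @param params model parameters.
#' @param state0 initial compartment state (default [initial_state()]).
#' @param horizon length of the run in weeks.
#' @param step integration step in weeks.
#' @param t0 start time in weeks.
#' @return A `"codep_trajectory"` with the parameters attached.
#' @examples
#' tr <- simulate_model(baseline_params(), horizon = 5)
#' utils::tail(as.data.frame(tr), 2)
#' @export
simulate_model <- function(params, state0 = initial_state(), horizon = 52,
                           step = 0.01, t0 = 0) {
  p <- .pvec(validate_params(params))
  y0 <- .svec(state0)
  names(y0) <- .COMPARTMENTS
  tr <- rk4_integrate(function(t, y) .rhs_unc(y, p), y0, t0, t0 + horizon,
                      step)
  tr$params <- p
  names(tr$params) <- .PARAM_NAMES
  tr
}

# Lock-step RK4 on a matrix of states (one row per trajectory / sample).
# P as in .rhs_unc_mat. Only the final states are returned.
.integrate_mat <- function(Y0, P, t0, t1, step) {
  times <- .time_grid(t0, t1, step)
  Y <- Y0
  for (i in seq_len(length(times) - 1L)) {
    h <- times[i + 1L] - times[i]
    k1 <- .rhs_unc_mat(Y, P)
    k2 <- .rhs_unc_mat(Y + (h / 2) * k1, P)
    k3 <- .rhs_unc_mat(Y + (h / 2) * k2, P)
    k4 <- .rhs_unc_mat(Y + h * k3, P)
    Y <- Y + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
    if (max(abs(Y)) > 1e12)
      stop("integration blow-up: state magnitude exceeded 1e12",
           call. = FALSE)
  }
  Y
}

#' @export
as.data.frame.codep_trajectory <- function(x, ...) {
  st <- x$states
  if (is.null(colnames(st)) && ncol(st) == 7L) colnames(st) <- .COMPARTMENTS
  data.frame(time = x$times, st, check.names = FALSE)
}

#' @export
print.codep_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("Model trajectory: %d time points on [%g, %g] weeks\n",
              n, x$times[1L], x$times[n]))
  cat("Final state:\n")
  print(round(x$states[n, ], 6))
  invisible(x)
}

#' @param x trajectory object.
#' @param which compartments to draw.
#' @param ... passed to [graphics::matplot()].
#' @rdname simulate_model
#' @export
plot.codep_trajectory <- function(x, which = .COMPARTMENTS, ...) {
  st <- x$states
  if (is.null(colnames(st))) colnames(st) <- .COMPARTMENTS
  which <- match.arg(which, colnames(st), several.ok = TRUE)
  graphics::matplot(x$times, st[, which, drop = FALSE], type = "l",
                    lty = 1, col = seq_along(which),
                    xlab = "time (weeks)", ylab = "compartment size", ...)
  graphics::legend("topright", legend = which, col = seq_along(which),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Total population along a trajectory
#'
#' @param trajectory a `"codep_trajectory"`.
#' @return Numeric vector `N(t) = S + D + M + Dm + Rd + Rm + Rdm`.
#' @export
total_population <- function(trajectory) {
  rowSums(trajectory$states)
}
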
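#' Normalized forward sensitivity index (elasticity)
#'
#' The elasticity of a reproduction number with respect to one parameter,
#' `(dR/dx) * (x/R)`: the fractional change in the target per fractional
#' change in the parameter. Computed from the closed forms
#' `R0D = a1*xi/(mu*(mu+phi1+delta1))` and
#' `R0M = a2*xi/(mu*(mu+phi2+delta2))`, whose nonzero elasticities are
#' `+1` for the contact rate and the recruitment rate,
#' `-x/(mu+phi+delta)` for the recovery and excess-death rates, and
#' `-1 - mu/(mu+phi+delta)` for the natural death rate. For the target
#' `"R0"` (the co-dependence number, `max(R0D, R0M)`), the index of the
#' dominant branch at the evaluation point is returned.
#'
#' @param target one of `"R0D"`, `"R0M"`, `"R0"`.
#' @param parameter a parameter name (see [model_params()]).
#' @param params model parameters.
#' @return One-row data frame with columns `target`, `parameter`, `index`.
#' @examples
#' forward_index("R0D", "mu", baseline_params())
#' @export
forward_index <- function(target = c("R0D", "R0M", "R0"), parameter,
                          params) {
  target <- match.arg(target)
  if (!parameter %in% .PARAM_NAMES)
    stop("unknown parameter: ", parameter, call. = FALSE)
  p <- .pvec(validate_params(params))
  if (target == "R0")
    target <- if (r0_drinkers(params) >= r0_smokers(params)) "R0D" else "R0M"
  if (target == "R0D") {
    q <- p[7L] + p[8L] + p[4L]
    idx <- switch(parameter,
                  a1 = 1, xi = 1,
                  mu = -1 - p[7L] / q,
                  phi1 = -p[8L] / q,
                  delta1 = -p[4L] / q,
                  0)
  } else {
    q <- p[7L] + p[9L] + p[5L]
    idx <- switch(parameter,
                  a2 = 1, xi = 1,
                  mu = -1 - p[7L] / q,
                  phi2 = -p[9L] / q,
                  delta2 = -p[5L] / q,
                  0)
  }
  data.frame(target = target, parameter = parameter, index = idx,
             stringsAsFactors = FALSE)
}

# Central-difference elasticity fallback (relative step), used as the
# in-suite oracle against the analytic indices.
.forward_index_fd <- function(target, parameter, params, h = 1e-6) {
  fun <- switch(target, R0D = r0_drinkers, R0M = r0_smokers,
                R0 = function(q) max(r0_drinkers(q), r0_smokers(q)))
  p <- .pvec(params)
  names(p) <- .PARAM_NAMES
  x <- p[[parameter]]
  if (x == 0) {
    # elasticity at zero: derivative * x / R is zero unless R vanishes
    return(0)
  }
  up <- p; up[[parameter]] <- x * (1 + h)
  dn <- p; dn[[parameter]] <- x * (1 - h)
  r <- fun(p)
  (fun(up) - fun(dn)) / (2 * h * x) * (x / r)
}

#' Full table of forward sensitivity indices
#'
#' Elasticities of both submodel reproduction numbers with respect to each
#' of the 13 model parameters.
#'
#' @param params model parameters.
#' @param targets subset of `c("R0D", "R0M")`.
#' @return Data frame with one row per (target, parameter).
#' @export
sensitivity_indices <- function(params, targets = c("R0D", "R0M")) {
  rows <- lapply(targets, function(tg)
    do.call(rbind, lapply(.PARAM_NAMES, forward_index, target = tg,
                          params = params)))
  do.call(rbind, rows)
}

#' Default sampling ranges for global sensitivity
#'
#' Each parameter uniform on `[lower, upper]` times its value in `params`:
#' a symmetric multiplicative band around the baseline (default +/- 25%),
#' used when no study-specific ranges are supplied.
#'
#' @param params model parameters.
#' @param lower,upper multiplicative band limits.
#' @return Named list of `c(low, high)` ranges.
#' @export
default_lhs_ranges <- function(params, lower = 0.75, upper = 1.25) {
  p <- .pvec(params)
  names(p) <- .PARAM_NAMES
  lapply(as.list(p), function(v) c(v * lower, v * upper))
}

#' Latin hypercube sample
#'
#' Stratified uniform sampling: for each parameter independently, one draw
#' from each of `n` equal-probability strata of the uniform distribution on
#' its range, with the stratum order permuted independently per parameter.
#' Bit-reproducible for a fixed `(ranges, n, seed)`.
#'
#' @param ranges named list of `c(low, high)` ranges.
#' @param n number of samples (>= 2).
#' @param seed RNG seed.
#' @return `n` x `length(ranges)` data frame of parameter draws.
#' @export
lhs_sample <- function(ranges, n, seed) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  k <- length(ranges)
  nm <- names(ranges)
  for (j in seq_len(k)) {
    r <- ranges[[j]]
    if (length(r) != 2L || !(r[1L] < r[2L]))
      stop("bad range for ", nm[j], ": low must be < high", call. = FALSE)
  }
  set.seed(seed)
  U <- lhs::randomLHS(n, k)
  X <- vapply(seq_len(k), function(j)
    stats::qunif(U[, j], ranges[[j]][1L], ranges[[j]][2L]), numeric(n))
  X <- as.data.frame(X)
  names(X) <- nm
  X
}

#' Partial rank correlation coefficients
#'
#' For each sampled parameter: rank-transform every column (average ranks
#' on ties), regress the parameter's ranks and the output's ranks on the
#' ranks of all other parameters, and return the correlation of the two
#' residual vectors. This is the partial Spearman correlation used in
#' LHS-PRCC uncertainty analysis; values lie in [-1, 1].
#'
#' @param samples data frame of parameter draws (one column per parameter).
#' @param outputs numeric vector of scalar model outputs, one per sample.
#' @param output_label label stored in the result.
#' @return Data frame with columns `parameter`, `coefficient`, `output`,
#'   `n_samples`.
#' @export
prcc <- function(samples, outputs, output_label = "output") {
  X <- as.matrix(samples)
  n <- nrow(X)
  if (length(outputs) != n)
    stop("outputs length must equal the sample count", call. = FALSE)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (any(apply(X, 2L, function(v) diff(range(v)) == 0)) ||
      diff(range(outputs)) == 0)
    stop("degenerate input: constant column", call. = FALSE)
  R <- apply(X, 2L, rank)
  ry <- rank(outputs)
  k <- ncol(R)
  coefs <- vapply(seq_len(k), function(j) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z))
      stop("degenerate input: rank-deficient design", call. = FALSE)
    ex <- qr.resid(qrz, R[, j])
    ey <- qr.resid(qrz, ry)
    stats::cor(ex, ey)
  }, numeric(1))
  data.frame(parameter = colnames(X), coefficient = coefs,
             output = output_label, n_samples = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Reproduction-number surface over a two-parameter grid
#'
#' Evaluates a reproduction number on the Cartesian grid of two parameters,
#' holding every other parameter at its value in `params`. This is the data
#' behind two-parameter response surfaces.
#'
#' @param target one of `"R0D"`, `"R0M"`, `"R0"`.
#' @param x_param,y_param parameter names.
#' @param x_grid,y_grid numeric grids (nonnegative).
#' @param params baseline parameters.
#' @return Data frame with columns `x_param`, `y_param` values and `value`.
#' @export
r0_surface <- function(target = c("R0D", "R0M", "R0"), x_param, y_param,
                       x_grid, y_grid, params) {
  target <- match.arg(target)
  if (!all(c(x_param, y_param) %in% .PARAM_NAMES))
    stop("unknown parameter name", call. = FALSE)
  if (!length(x_grid) || !length(y_grid))
    stop("empty grid", call. = FALSE)
  fun <- switch(target, R0D = r0_drinkers, R0M = r0_smokers,
                R0 = function(q) max(r0_drinkers(q), r0_smokers(q)))
  p <- .pvec(params)
  names(p) <- .PARAM_NAMES
  grid <- expand.grid(x = x_grid, y = y_grid)
  grid$value <- vapply(seq_len(nrow(grid)), function(i) {
    q <- p
    q[[x_param]] <- grid$x[i]
    q[[y_param]] <- grid$y[i]
    fun(q)
  }, numeric(1))
  names(grid)[1:2] <- c(x_param, y_param)
  grid
}

#' Percentile summary of a sampled output
#'
#' The 2.5, 25, 50, 75 and 97.5 percentiles of a scalar output sample; the
#' outer pair is the central 95% uncertainty interval.
#'
#' @param outputs numeric sample (>= 20 values).
#' @return Named numeric vector of percentiles.
#' @export
r0_uncertainty <- function(outputs) {
  if (length(outputs) < 20)
    stop("too few samples: need at least 20", call. = FALSE)
  stats::quantile(outputs, c(0.025, 0.25, 0.5, 0.75, 0.975), names = TRUE)
}

#' Global sensitivity analysis of reproduction numbers and trajectories
#'
#' Draws a Latin hypercube sample of all 13 parameters (independently, so
#' the structural identities on `phi3`/`gamma3` are released for the
#' uncertainty analysis), evaluates the requested scalar outputs per
#' sample, and returns the PRCC table per output together with the
#' percentile summary of the co-dependence reproduction number.
#'
#' Reproduction-number outputs are closed-form; the trajectory outputs
#' `"D", "M", "Dm"` are the corresponding compartments at `eval_time`
#' weeks, obtained by integrating all samples in lock-step from `state0`.
#'
#' @param params baseline parameters around which ranges are built.
#' @param n sample size.
#' @param seed RNG seed.
#' @param ranges named list of ranges (default [default_lhs_ranges()]).
#' @param outputs subset of `c("R0D", "R0M", "R0", "D", "M", "Dm")`.
#' @param state0 initial state for trajectory outputs.
#' @param eval_time evaluation time (weeks) for trajectory outputs.
#' @param step integration step for trajectory outputs.
#' @return List of class `"codep_gsa"`: `samples`, `outputs` (data frame),
#'   `prcc` (one data frame per output), `summary` (percentiles of R0 when
#'   computed).
#' @export
global_sensitivity <- function(params = baseline_params(), n = 2000,
                               seed = 20241219,
                               ranges = default_lhs_ranges(params),
                               outputs = c("R0D", "R0M", "R0"),
                               state0 = initial_state(), eval_time = 52,
                               step = 0.02) {
  outputs <- match.arg(outputs, c("R0D", "R0M", "R0", "D", "M", "Dm"),
                       several.ok = TRUE)
  samples <- lhs_sample(ranges, n, seed)
  P <- as.matrix(samples[, .PARAM_NAMES, drop = FALSE])
  out <- list()
  if (any(c("R0D", "R0M", "R0") %in% outputs)) {
    r0d <- P[, "a1"] * P[, "xi"] /
      (P[, "mu"] * (P[, "mu"] + P[, "phi1"] + P[, "delta1"]))
    r0m <- P[, "a2"] * P[, "xi"] /
      (P[, "mu"] * (P[, "mu"] + P[, "phi2"] + P[, "delta2"]))
    if ("R0D" %in% outputs) out$R0D <- r0d
    if ("R0M" %in% outputs) out$R0M <- r0m
    if ("R0" %in% outputs) out$R0 <- pmax(r0d, r0m)
  }
  if (any(c("D", "M", "Dm") %in% outputs)) {
    Y0 <- matrix(.svec(state0), n, 7L, byrow = TRUE)
    Yend <- .integrate_mat(Y0, P, 0, eval_time, step)
    colnames(Yend) <- .COMPARTMENTS
    for (v in intersect(c("D", "M", "Dm"), outputs)) out[[v]] <- Yend[, v]
  }
  out <- as.data.frame(out)[outputs]
  prcc_tabs <- lapply(outputs, function(v)
    prcc(samples, out[[v]], output_label = v))
  names(prcc_tabs) <- outputs
  structure(list(samples = samples, outputs = out, prcc = prcc_tabs,
                 summary = if ("R0" %in% outputs) r0_uncertainty(out$R0),
                 seed = seed, n = n),
            class = "codep_gsa")
}

#' @export
print.codep_gsa <- function(x, ...) {
  cat(sprintf("Global sensitivity analysis: n = %d, seed = %d\n", x$n,
              x$seed))
  for (v in names(x$prcc)) {
    tab <- x$prcc[[v]]
    tab <- tab[order(-abs(tab$coefficient)), ]
    top <- utils::head(tab, 5L)
    cat(sprintf("  %s: top PRCC %s\n", v,
                paste(sprintf("%s=%+.3f", top$parameter, top$coefficient),
                      collapse = ", ")))
  }
  if (!is.null(x$summary)) {
    cat("  R0 percentiles:\n")
    print(round(x$summary, 4))
  }
  invisible(x)
}
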
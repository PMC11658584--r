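# Shared fixtures: baseline parameters and small random-case generators.

bp <- baseline_params()

# Random parameter sets log-uniform on [0.2x, 5x] the baseline, with the
# structural identities released so all 13 rates vary freely.
random_params <- function(n, seed) {
  set.seed(seed)
  base <- as.numeric(bp)
  names(base) <- names(bp)
  lapply(seq_len(n), function(i) {
    f <- exp(stats::runif(13, log(0.2), log(5)))
    vals <- as.list(base * f)
    do.call(model_params, c(vals, assume_identities = FALSE))
  })
}

random_state <- function(scale = 2) {
  model_state(S = runif(1, 0, scale), D = runif(1, 0, scale),
              M = runif(1, 0, scale), Dm = runif(1, 0, scale),
              Rd = runif(1, 0, scale), Rm = runif(1, 0, scale),
              Rdm = runif(1, 0, scale))
}

# Central-difference gradient of the Hamiltonian in the state (exact for
# this quadratic H, up to roundoff).
fd_adjoint <- function(y, u, l, params, weights, h = 1e-4) {
  vapply(1:7, function(i) {
    yp <- y; ym <- y
    yp[i] <- y[i] + h
    ym[i] <- y[i] - h
    -(hamiltonian(yp, u, l, params, weights) -
        hamiltonian(ym, u, l, params, weights)) / (2 * h)
  }, numeric(1))
}

fd_hamiltonian_du <- function(y, u, l, params, weights, h = 1e-4) {
  vapply(1:5, function(k) {
    up <- u; um <- u
    up[k] <- u[k] + h
    um[k] <- u[k] - h
    (hamiltonian(y, up, l, params, weights) -
       hamiltonian(y, um, l, params, weights)) / (2 * h)
  }, numeric(1))
}
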
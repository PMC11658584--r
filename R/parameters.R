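#' @keywords internal
".PARAM_NAMES" <- c("xi", "a1", "a2", "delta1", "delta2", "k1", "mu",
                    "phi1", "phi2", "phi3", "gamma1", "gamma2", "gamma3")

#' @keywords internal
".COMPARTMENTS" <- c("S", "D", "M", "Dm", "Rd", "Rm", "Rdm")

#' Model parameter set
#'
#' Construct and validate the 13 rate constants of the drinking-smoking
#' co-dependence model. All rates are per week. Defaults are the literature
#' baseline used throughout the package (see [baseline_params()]).
#'
#' Two composite rates are tied to the others by the model's structural
#' assumptions: the co-dependence-induced death rate `phi3 = phi1 + phi2`
#' (the two habits' excess mortalities add) and the co-dependent relapse
#' rate `gamma3 = (gamma1 + gamma2) / 2` (estimated as the mean of the two
#' single-habit relapse rates). When `assume_identities = TRUE` (the
#' default), omitted values are derived from these identities and supplied
#' values are checked against them to relative tolerance 1e-12. Set
#' `assume_identities = FALSE` to supply free values, e.g. when sampling
#' all 13 rates independently.
#'
#' @param xi recruitment rate into the susceptible class.
#' @param a1 contact (interaction) rate of drinkers.
#' @param a2 contact rate of smokers.
#' @param delta1 recovery rate of drinkers.
#' @param delta2 recovery rate of smokers.
#' @param k1 recovery rate of co-dependent individuals.
#' @param mu natural death rate (must be positive).
#' @param phi1 drinking-induced death rate.
#' @param phi2 smoking-induced death rate.
#' @param phi3 co-dependence-induced death rate; `NULL` derives `phi1 + phi2`.
#' @param gamma1 relapse rate Rd -> S.
#' @param gamma2 relapse rate Rm -> S.
#' @param gamma3 relapse rate Rdm -> S; `NULL` derives `(gamma1 + gamma2)/2`.
#' @param assume_identities enforce the `phi3`/`gamma3` identities.
#' @return A named numeric vector of class `"codep_params"`.
#' @examples
#' p <- model_params()
#' p[["phi3"]] - (p[["phi1"]] + p[["phi2"]])
#' @export
model_params <- function(xi = 0.8, a1 = 0.00479, a2 = 0.035,
                         delta1 = 0.00767, delta2 = 0.217, k1 = 0.01923,
                         mu = 0.0952, phi1 = 0.000009, phi2 = 0.175,
                         phi3 = NULL, gamma1 = 0.7, gamma2 = 0.00575,
                         gamma3 = NULL, assume_identities = TRUE) {
  if (is.null(phi3)) phi3 <- phi1 + phi2
  if (is.null(gamma3)) gamma3 <- (gamma1 + gamma2) / 2
  p <- c(xi = xi, a1 = a1, a2 = a2, delta1 = delta1, delta2 = delta2,
         k1 = k1, mu = mu, phi1 = phi1, phi2 = phi2, phi3 = phi3,
         gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3)
  validate_params(p, assume_identities = assume_identities)
  structure(p, class = "codep_params")
}

#' Baseline parameter preset
#'
#' The week^-1 literature baseline parameter set used for all worked examples:
#' xi = 0.8, a1 = 0.00479, a2 = 0.035, delta1 = 0.00767, delta2 = 0.217,
#' k1 = 0.01923, mu = 0.0952, phi1 = 9e-6, phi2 = 0.175,
#' phi3 = phi1 + phi2 = 0.175009, gamma1 = 0.7, gamma2 = 0.00575,
#' gamma3 = 0.352875.
#'
#' @return A `"codep_params"` vector.
#' @export
baseline_params <- function() model_params()

#' Validate a parameter vector
#'
#' @param p named numeric vector with the 13 model rates.
#' @param assume_identities check `phi3 = phi1 + phi2` and
#'   `gamma3 = (gamma1 + gamma2)/2` to relative tolerance 1e-12.
#' @return `p`, invisibly, after checks.
#' @export
validate_params <- function(p, assume_identities = FALSE) {
  if (!is.numeric(p)) stop("parameters must be numeric", call. = FALSE)
  missing <- setdiff(.PARAM_NAMES, names(p))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(p), .PARAM_NAMES)
  if (length(extra))
    stop("unknown parameters: ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (anyNA(p) || any(!is.finite(p)))
    stop("parameters must be finite", call. = FALSE)
  neg <- names(p)[p < 0]
  if (length(neg))
    stop("negative parameters: ", paste(neg, collapse = ", "),
         call. = FALSE)
  if (p[["mu"]] <= 0) stop("mu must be > 0", call. = FALSE)
  if (p[["xi"]] <= 0) stop("xi must be > 0", call. = FALSE)
  if (assume_identities) {
    .check_identity(p[["phi3"]], p[["phi1"]] + p[["phi2"]], "phi3")
    .check_identity(p[["gamma3"]], (p[["gamma1"]] + p[["gamma2"]]) / 2,
                    "gamma3")
  }
  invisible(p)
}

.check_identity <- function(value, expected, name, rtol = 1e-12) {
  if (abs(value - expected) > rtol * max(1, abs(expected)))
    stop(sprintf("%s = %.12g is inconsistent with its structural identity (expected %.12g)",
                 name, value, expected), call. = FALSE)
}

#' @export
print.codep_params <- function(x, ...) {
  cat("Drinking-smoking co-dependence model parameters (week^-1):\n")
  print(round(unclass(x), 8))
  invisible(x)
}

#' Compartment state vector
#'
#' A named state (S, D, M, Dm, Rd, Rm, Rdm): susceptible, drinkers, smokers,
#' co-dependent, recovered drinkers, recovered smokers, recovered
#' co-dependent. Components must be nonnegative and finite.
#'
#' @param S,D,M,Dm,Rd,Rm,Rdm compartment sizes (population units).
#' @return Named numeric vector of length 7.
#' @export
model_state <- function(S = 0, D = 0, M = 0, Dm = 0, Rd = 0, Rm = 0,
                        Rdm = 0) {
  y <- c(S = S, D = D, M = M, Dm = Dm, Rd = Rd, Rm = Rm, Rdm = Rdm)
  if (anyNA(y) || any(!is.finite(y)))
    stop("state components must be finite", call. = FALSE)
  if (any(y < 0)) stop("state components must be nonnegative", call. = FALSE)
  y
}

#' Baseline initial condition
#'
#' The initial condition used in the package's reference scenario:
#' S = 0.6, D = 0.2, M = 0.1, Dm = 0.06, Rd = 0.02, Rm = 0, Rdm = 0.
#'
#' @return Named numeric state vector.
#' @export
initial_state <- function() {
  model_state(S = 0.6, D = 0.2, M = 0.1, Dm = 0.06, Rd = 0.02)
}

# Coerce parameters to a bare double vector in canonical order (hot paths).
.pvec <- function(p) {
  as.numeric(p[.PARAM_NAMES])
}

.svec <- function(y) {
  if (!is.null(names(y)) && all(.COMPARTMENTS %in% names(y)))
    y <- y[.COMPARTMENTS]
  if (length(y) != 7L) stop("state must have 7 components", call. = FALSE)
  as.numeric(y)
}
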
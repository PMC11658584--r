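#' Load a scenario configuration
#'
#' Reads a YAML scenario file with any subset of the keys `parameters`
#' (flat mapping of the 13 rate names), `initial_state`, `horizon`, `step`,
#' `weights`, `control_bounds`, `enabled_controls`, `lhs` (`ranges`,
#' `n_samples`, `seed`) and `output_dir`. Missing entries fall back to the package
#' defaults (baseline parameters, reference initial state, 52-week horizon
#' at step 0.01, reference objective weights, all controls enabled on
#' [0, 1]). Unknown keys anywhere in the file are rejected so parameter
#' typos cannot pass silently; a `phi3` or `gamma3` that contradicts its
#' structural identity is a validation error naming the field.
#'
#' @param path path to a YAML file, or `NULL` for the pure defaults.
#' @return List of class `"codep_config"` with fully validated entries.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("config parse error: ", conditionMessage(e), call. = FALSE))
    if (is.null(cfg)) list() else cfg
  }
  allowed <- c("parameters", "initial_state", "horizon", "step", "weights",
               "control_bounds", "enabled_controls", "lhs", "output_dir")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  pars <- raw$parameters
  if (!is.null(pars)) {
    bad <- setdiff(names(pars), .PARAM_NAMES)
    if (length(bad))
      stop("unknown parameters in config: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  params <- tryCatch(
    do.call(model_params, as.list(pars)),
    error = function(e) stop("config validation error in parameters: ",
                             conditionMessage(e), call. = FALSE))

  st <- raw$initial_state
  if (!is.null(st)) {
    bad <- setdiff(names(st), .COMPARTMENTS)
    if (length(bad))
      stop("unknown initial_state fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  state0 <- do.call(model_state, utils::modifyList(
    as.list(initial_state()), as.list(st)))

  horizon <- raw$horizon %||% 52
  step <- raw$step %||% 0.01
  if (!(horizon > 0)) stop("horizon must be > 0", call. = FALSE)
  if (!(step > 0)) stop("step must be > 0", call. = FALSE)

  wt <- raw$weights
  if (!is.null(wt)) {
    bad <- setdiff(names(wt), c("A1", "A2", "A3", paste0("w", 1:5)))
    if (length(bad))
      stop("unknown weight fields: ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  weights <- do.call(objective_weights, as.list(wt))

  enabled <- raw$enabled_controls %||% 1:5
  if (is.character(enabled)) enabled <- match(enabled, paste0("u", 1:5))
  if (anyNA(enabled) || !length(enabled) || !all(enabled %in% 1:5))
    stop("enabled_controls must be a nonempty subset of u1..u5",
         call. = FALSE)
  bounds <- if (is.null(raw$control_bounds)) {
    control_bounds(enabled = enabled)
  } else {
    b <- .bounds_matrix(do.call(cbind, raw$control_bounds))
    b[, setdiff(1:5, enabled)] <- 0
    b
  }

  lhs_cfg <- raw$lhs %||% list()
  # the sample count key is "n_samples", not "n": a bare "n" is a YAML 1.1
  # boolean token and would not survive parsing
  bad <- setdiff(names(lhs_cfg), c("ranges", "n_samples", "seed"))
  if (length(bad))
    stop("unknown lhs fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  lhs_cfg <- list(
    ranges = lhs_cfg$ranges %||% default_lhs_ranges(params),
    n = lhs_cfg$n_samples %||% 2000,
    seed = lhs_cfg$seed %||% 20241219)

  structure(list(parameters = params, initial_state = state0,
                 horizon = horizon, step = step, weights = weights,
                 control_bounds = bounds, enabled_controls = enabled,
                 lhs = lhs_cfg, output_dir = raw$output_dir %||% "."),
            class = "codep_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory table
#'
#' Writes a delimited table with header `time,S,D,M,Dm,Rd,Rm,Rdm`, plus
#' `u1..u5` columns when controls are supplied, one row per grid point at
#' full floating precision (round-trips losslessly through
#' [read_trajectory()]). Nothing is left behind on failure.
#'
#' @param trajectory a `"codep_trajectory"` (or `"codep_oc"`, whose
#'   controls are written automatically unless overridden).
#' @param path output file path.
#' @param controls optional n x 5 control matrix.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, controls = NULL) {
  if (inherits(trajectory, "codep_oc")) {
    if (is.null(controls)) controls <- trajectory$controls
    trajectory <- list(times = trajectory$times,
                       states = trajectory$states)
  }
  st <- trajectory$states
  if (is.null(colnames(st))) colnames(st) <- .COMPARTMENTS
  tab <- cbind(time = trajectory$times, st)
  if (!is.null(controls)) {
    controls <- as.matrix(controls)
    if (nrow(controls) != length(trajectory$times))
      stop("grid mismatch between trajectory and controls", call. = FALSE)
    colnames(controls) <- paste0("u", seq_len(ncol(controls)))
    tab <- cbind(tab, controls)
  }
  lines <- c(paste(colnames(tab), collapse = ","),
             apply(tab, 1L, function(r)
               paste(sprintf("%.17g", r), collapse = ",")))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("io-error: cannot open ", path, " for writing", call. = FALSE),
    warning = function(e)
      stop("io-error: cannot open ", path, " for writing", call. = FALSE))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a trajectory table written by [write_trajectory()]
#'
#' @param path file path.
#' @return A `"codep_trajectory"`; any `u*` columns are attached as the
#'   `controls` element.
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  ucols <- grep("^u[0-9]+$", names(tab))
  tr <- structure(list(times = tab$time,
                       states = as.matrix(tab[.COMPARTMENTS])),
                  class = "codep_trajectory")
  if (length(ucols)) tr$controls <- as.matrix(tab[ucols])
  tr
}

#' Write a run manifest
#'
#' Echoes the configuration, seed and package version to a YAML file so a
#' run can be replayed exactly.
#'
#' @param config a `"codep_config"`.
#' @param path output path.
#' @param seed the seed the run used.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(config, path, seed = NULL) {
  man <- list(
    package = "codepend",
    version = as.character(utils::packageVersion("codepend")),
    seed = seed,
    parameters = as.list(unclass(config$parameters)),
    initial_state = as.list(config$initial_state),
    horizon = config$horizon, step = config$step,
    weights = as.list(unclass(config$weights)),
    enabled_controls = config$enabled_controls,
    lhs = list(n_samples = config$lhs$n, seed = config$lhs$seed))
  yaml::write_yaml(man, path)
  invisible(path)
}
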
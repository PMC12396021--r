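# Parameter sets and stress protocols.

# canonical parameter order, shared with the compiled derivative function
.beclin_par_order <- c(
  "S", "alpha_B", "beta_B", "gamma_B", "gamma_BC",
  "alpha_A", "beta_A", "phi_A",
  "alpha_M", "sigma_M", "gamma_M",
  "alpha_C", "sigma_C", "mu_C", "gamma_C", "phi_C",
  "sigma_J", "u_B", "u_M"
)

# parameters held fixed (not sampled): they pin the bistable Caspase switch
.beclin_fixed_pars <- c(mu_C = 1, gamma_C = 0.3, phi_C = 0.15)

#' Construct a model parameter set
#'
#' A parameter set describes one simulated cell variant: per-hour rate
#' constants for Beclin-1 turnover and cleavage, autophagosome biogenesis
#' and saturable clearance, mitochondrial damage and mitophagy, and the
#' Caspase-3 activation switch, plus the stress level `S` and the stress
#' sensitivities `u_B` (Beclin-1 expression) and `u_M` (mitochondrial
#' damage). Defaults are the representative ("R") variant. The Caspase
#' switch constants `mu_C`, `gamma_C`, `phi_C` default to the values that
#' make the unforced Caspase subsystem bistable (see [caspase_cond1()]).
#'
#' @param ... named parameter overrides; unknown names are an error.
#' @return a named list of class `beclin_params`.
#' @examples
#' p <- beclin_params(alpha_B = 2)
#' p$alpha_B
#' @export
beclin_params <- function(...) {
  p <- list(
    S = 1,
    alpha_B = 1, beta_B = 1, gamma_B = 1, gamma_BC = 1,
    alpha_A = 1, beta_A = 1, phi_A = 10,
    alpha_M = 1, sigma_M = 50, gamma_M = 1,
    alpha_C = 0.005, sigma_C = 0.001,
    mu_C = 1, gamma_C = 0.3, phi_C = 0.15,
    sigma_J = 0.01, u_B = 1, u_M = 1
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == ""))
      stop("all parameter overrides must be named")
    bad <- setdiff(names(ov), names(p))
    if (length(bad))
      stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  validate_params(p)
  structure(p, class = "beclin_params")
}

#' The representative (R) parameter variant
#'
#' The single parameter set used for the viability-window, perturbation and
#' golden-hour analyses: all rate constants at their representative values
#' (most of them 1 per hour, `phi_A = 10`, `sigma_M = 50`, `alpha_C = 0.005`,
#' `sigma_C = 0.001`, `sigma_J = 0.01`), with the fixed Caspase constants.
#'
#' @return a `beclin_params` object.
#' @export
r_variant <- function() beclin_params()

validate_params <- function(p) {
  need <- .beclin_par_order
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))
  v <- unlist(p[need])
  if (!is.numeric(v) || anyNA(v))
    stop("parameters must be numeric and non-missing")
  if (any(v < 0))
    stop("parameters must be nonnegative; offending: ",
         paste(need[v < 0], collapse = ", "))
  if (p$phi_C <= 0) stop("phi_C must be positive")
  invisible(p)
}

# flat named numeric vector in canonical order, with S replaced if asked
par_vector <- function(p, S = p$S) {
  v <- unlist(p[.beclin_par_order])
  v[["S"]] <- S
  v
}

#' @export
print.beclin_params <- function(x, ...) {
  cat("<beclin_params>\n")
  print(unlist(x[.beclin_par_order]))
  invisible(x)
}

#' Piecewise-constant ischemic stress protocol
#'
#' Stress `S(t)` equals `level` on `[t_on, t_off)` and 0 elsewhere, over a
#' total simulated horizon. The ensemble experiments use stress on
#' \[0, 24\] h of a 48 h simulation; golden-hour runs vary `t_off`.
#'
#' @param level stress magnitude while on (>= 0).
#' @param t_on,t_off onset and offset times (h), `0 <= t_on <= t_off <= horizon`.
#' @param horizon total simulated time (h).
#' @return an object of class `stress_protocol`.
#' @examples
#' stress_protocol(level = 8, t_off = 4.8)
#' @export
stress_protocol <- function(level, t_on = 0, t_off = 24, horizon = 48) {
  stopifnot(is.numeric(level), length(level) == 1, level >= 0)
  if (!(0 <= t_on && t_on <= t_off && t_off <= horizon))
    stop("need 0 <= t_on <= t_off <= horizon")
  structure(list(level = level, t_on = t_on, t_off = t_off, horizon = horizon),
            class = "stress_protocol")
}

#' Stress level at given times
#'
#' @param protocol a [stress_protocol()].
#' @param t vector of times (h).
#' @return numeric vector of S(t).
#' @export
stress_at <- function(protocol, t) {
  ifelse(t >= protocol$t_on & t < protocol$t_off, protocol$level, 0)
}

#' @export
print.stress_protocol <- function(x, ...) {
  cat(sprintf("<stress_protocol> S = %g on [%g, %g) h, horizon %g h\n",
              x$level, x$t_on, x$t_off, x$horizon))
  invisible(x)
}

#' Read / write parameter sets as flat key-value files
#'
#' Parameter sets are persisted as flat JSON (or YAML) maps whose keys are
#' the ASCII parameter names (`alpha_B`, `phi_A`, ...).
#'
#' @param p a `beclin_params` object.
#' @param path file path; format chosen by extension (`.json` or `.yaml`/`.yml`).
#' @return `read_params` returns a `beclin_params`; `write_params` returns
#'   the path invisibly.
#' @export
write_params <- function(p, path) {
  validate_params(p)
  vals <- as.list(unlist(p[.beclin_par_order]))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML output")
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required for YAML input")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(beclin_params, as.list(vals))
}
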
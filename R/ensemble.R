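# Virtual populations: Latin-hypercube parameter variants, knockout
# scenarios, and noise-perturbed Beclin-1 expression populations.

#' Sampling ranges of the model parameters
#'
#' Per-parameter (low, high) bounds used for the Latin-hypercube ensembles.
#' Fourteen parameters are sampled by default. The three Caspase switch
#' constants (`mu_C`, `gamma_C`, `phi_C`) are never sampled: varying them
#' would break the bistability of the switch. The two stress sensitivities
#' (`u_B`, `u_M`) are held at their representative value 1 by default —
#' this is what makes the sampled count fourteen, and the ensemble
#' apoptotic fractions corroborate it; plausible ranges for them are
#' nevertheless tabulated and can be included.
#'
#' @param include_stress_sensitivities also sample `u_B` and `u_M` over
#'   \[0.5, 2\] (sixteen sampled parameters).
#' @return named list of length-2 numeric vectors `c(low, high)`.
#' @export
sampling_ranges <- function(include_stress_sensitivities = FALSE) {
  r <- list(
    S = c(0, 10),
    alpha_B = c(0.1, 5), beta_B = c(0.5, 2), gamma_B = c(0.5, 2),
    gamma_BC = c(0.5, 2),
    alpha_A = c(0.5, 2), beta_A = c(0.5, 2), phi_A = c(5, 20),
    alpha_M = c(0.5, 2), sigma_M = c(25, 100), gamma_M = c(0.5, 2),
    alpha_C = c(0.0025, 0.01), sigma_C = c(0.0005, 0.002),
    sigma_J = c(0.005, 0.02)
  )
  if (include_stress_sensitivities)
    r <- c(r, list(u_B = c(0.5, 2), u_M = c(0.5, 2)))
  r
}

#' Latin-hypercube parameter ensemble
#'
#' Draws `n` parameter variants by Latin hypercube sampling: each sampled
#' parameter's unit interval is divided into `n` equal strata containing
#' exactly one draw, and the unit samples are mapped to the parameter
#' ranges by linear interpolation. The fixed Caspase constants are appended
#' unchanged. Sampling is uniform on the linear scale for every parameter.
#'
#' @param n number of variants.
#' @param seed RNG seed (the ensemble is deterministic given the seed).
#' @param ranges sampling ranges, as from [sampling_ranges()].
#' @return data.frame with a `variant` id column, one column per sampled
#'   parameter, and the fixed `mu_C`, `gamma_C`, `phi_C` columns; attribute
#'   `seed` records the seed.
#' @examples
#' ens <- sample_ensemble(100, seed = 1234)
#' colMeans(ens[, c("alpha_B", "phi_A")])
#' @export
sample_ensemble <- function(n, seed = 1234, ranges = sampling_ranges()) {
  stopifnot(n >= 1)
  bad <- names(ranges)[vapply(ranges, function(r) r[1] >= r[2], logical(1))]
  if (length(bad)) stop("invalid range (low >= high) for: ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  u <- lhs::randomLHS(n, length(ranges))
  vals <- mapply(function(j, r) r[1] + u[, j] * (r[2] - r[1]),
                 seq_along(ranges), ranges, SIMPLIFY = FALSE)
  ens <- as.data.frame(setNames(vals, names(ranges)))
  for (nm in names(.beclin_fixed_pars)) ens[[nm]] <- .beclin_fixed_pars[[nm]]
  for (nm in setdiff(c("u_B", "u_M"), names(ranges))) ens[[nm]] <- 1
  ens <- cbind(variant = seq_len(n), ens)
  attr(ens, "seed") <- seed
  ens
}

# one row of an ensemble as a beclin_params object
variant_params <- function(ensemble, i) {
  row <- as.list(ensemble[i, .beclin_par_order])
  do.call(beclin_params, row)
}

#' Scenario specification
#'
#' A named map of parameter overrides applied uniformly to every variant of
#' an ensemble after sampling (paired design: non-overridden parameters stay
#' bit-identical across scenarios).
#'
#' @param name scenario label.
#' @param overrides named numeric vector/list of parameter overrides (empty
#'   for the wild type).
#' @return an object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, overrides = list()) {
  overrides <- as.list(overrides)
  bad <- setdiff(names(overrides), .beclin_par_order)
  if (length(overrides) && length(bad))
    stop("unknown override key(s): ", paste(bad, collapse = ", "))
  structure(list(name = name, overrides = overrides), class = "scenario_spec")
}

#' The eight canonical knockout/saturation scenarios
#'
#' The cross of flux saturation (normal `phi_A` versus `phi_A = 1e6`, which
#' makes the autophagic flux effectively unsaturable) with the three
#' pro-apoptotic mechanism knockouts: mechanism 1 (Caspase-mediated Beclin-1
#' cleavage, `beta_B = 0`), mechanism 2 (autophagosome-mediated Caspase
#' activation, `sigma_C = 0`), mechanism 3 (autophagic IAP degradation,
#' `sigma_J = 0`).
#'
#' @return named list of eight [scenario_spec()] objects.
#' @export
canonical_scenarios <- function() {
  specs <- list(
    scenario_spec("wild-type"),
    scenario_spec("no-mech1", c(beta_B = 0)),
    scenario_spec("no-mech2", c(sigma_C = 0)),
    scenario_spec("no-mech3", c(sigma_J = 0)),
    scenario_spec("no-saturation", c(phi_A = 1e6)),
    scenario_spec("no-saturation+no-mech1", c(phi_A = 1e6, beta_B = 0)),
    scenario_spec("no-saturation+no-mech2", c(phi_A = 1e6, sigma_C = 0)),
    scenario_spec("no-saturation+no-mech3", c(phi_A = 1e6, sigma_J = 0))
  )
  setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Apply a scenario to an ensemble
#'
#' @param ensemble data.frame from [sample_ensemble()].
#' @param scenario a [scenario_spec()].
#' @return the ensemble with the overridden columns replaced; all other
#'   columns are returned untouched.
#' @export
apply_scenario <- function(ensemble, scenario) {
  stopifnot(inherits(scenario, "scenario_spec"))
  for (key in names(scenario$overrides))
    ensemble[[key]] <- scenario$overrides[[key]]
  attr(ensemble, "scenario") <- scenario$name
  ensemble
}

#' Noise-perturbed Beclin-1 expression population
#'
#' Emulates cell-to-cell variability in an in-silico knockdown or
#' overexpression experiment: `n` copies of a base variant whose Beclin-1
#' expression rate is scaled by `fold` (2 = overexpression, 0.5 = knockdown)
#' and perturbed by Gaussian noise, truncated at zero:
#' `alpha_B' = max(0, fold * alpha_B + eps)`, `eps ~ N(0, noise_sd^2)`.
#'
#' @param base a [beclin_params()] set.
#' @param fold multiplier on the basal expression rate (> 0).
#' @param n population size.
#' @param noise_sd standard deviation of the additive noise.
#' @param seed RNG seed.
#' @return data.frame with columns `cell` and `alpha_B` (the remaining
#'   parameters are those of `base`), attribute `base`.
#' @export
perturbed_population <- function(base, fold, n, noise_sd = 0.5, seed = 1) {
  stopifnot(fold > 0, n >= 1, noise_sd >= 0)
  validate_params(base)
  set.seed(seed)
  a <- pmax(0, fold * base$alpha_B + rnorm(n, 0, noise_sd))
  structure(data.frame(cell = seq_len(n), alpha_B = a), base = base)
}

#' Write / read an ensemble as CSV
#'
#' One row per variant, one column per parameter, plus the `variant` id
#' (and `scenario` label when present).
#'
#' @param ensemble data.frame from [sample_ensemble()] (possibly with a
#'   scenario applied).
#' @param path CSV file path.
#' @return `read_ensemble` returns the data.frame; `write_ensemble` the
#'   path, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  out <- ensemble
  sc <- attr(ensemble, "scenario")
  if (!is.null(sc)) out$scenario <- sc
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
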
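# In-silico experiments: scenario ensembles, stress-stratified apoptosis,
# viability windows, perturbation populations, parameter sensitivity, and
# golden-hour duration thresholds.

# default protocol of the ensemble experiments: stress on [0, 24] h of a
# 48 h simulation, apoptosis read out at 48 h
default_protocol <- function(level = 0) stress_protocol(level, 0, 24, 48)

#' Apoptotic fractions across scenarios on a paired ensemble
#'
#' Simulates every variant of a shared ensemble under each scenario (paired
#' design: the same variants, differing only in the scenario overrides).
#' Each variant starts from its unstressed steady state under the scenario's
#' parameters and experiences its own sampled stress `S` on
#' `[t_on, t_off]`; apoptosis is a 48-h Caspase-3 level above 0.5.
#'
#' Variants that are degenerate (no resting autophagy balance, see
#' [unstressed_steady_state()]) under any scenario are excluded from every
#' scenario, so numerators and denominators stay paired; exclusion counts
#' are reported in the `exclusions` attribute.
#'
#' @param ensemble data.frame from [sample_ensemble()].
#' @param scenarios list of [scenario_spec()]s (default the canonical eight).
#' @param protocol protocol template; each variant's own `S` replaces its
#'   level.
#' @param rtol,atol solver tolerances.
#' @return data.frame (class `scenario_fractions`) with columns `scenario`,
#'   `n`, `n_apoptotic`, `fraction`, `ci_lo`, `ci_hi`; attributes `outcomes`
#'   (per-variant logical outcome per scenario, with `S` and `alpha_B`),
#'   `exclusions` (per-scenario degenerate counts) and `excluded_variants`.
#' @export
scenario_fractions <- function(ensemble, scenarios = canonical_scenarios(),
                               protocol = default_protocol(),
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(nrow(ensemble) >= 1, length(scenarios) >= 1)
  n <- nrow(ensemble)
  sc_names <- vapply(scenarios, `[[`, character(1), "name")
  outcome <- matrix(NA, n, length(scenarios),
                    dimnames = list(NULL, sc_names))
  degenerate <- matrix(FALSE, n, length(scenarios),
                       dimnames = list(NULL, sc_names))
  for (j in seq_along(scenarios)) {
    ens_j <- apply_scenario(ensemble, scenarios[[j]])
    for (i in seq_len(n)) {
      p <- variant_params(ens_j, i)
      ss <- unstressed_steady_state(p)
      if (ss$degenerate) { degenerate[i, j] <- TRUE; next }
      proto <- stress_protocol(p$S, protocol$t_on, protocol$t_off,
                               protocol$horizon)
      outcome[i, j] <- final_caspase(p, proto, ss$state,
                                     rtol = rtol, atol = atol) > 0.5
    }
  }
  excluded <- apply(degenerate, 1, any)
  keep <- !excluded
  res <- do.call(rbind, lapply(seq_along(scenarios), function(j) {
    k <- sum(outcome[keep, j]); m <- sum(keep)
    ci <- proportion_ci(k, m)
    data.frame(scenario = sc_names[j], n = m, n_apoptotic = k,
               fraction = k / m, ci_lo = ci[1], ci_hi = ci[2])
  }))
  rownames(res) <- NULL
  out_df <- data.frame(variant = ensemble$variant, S = ensemble$S,
                       alpha_B = ensemble$alpha_B, excluded = excluded)
  out_df <- cbind(out_df, as.data.frame(outcome))
  attr(res, "outcomes") <- out_df
  attr(res, "exclusions") <- colSums(degenerate)
  attr(res, "excluded_variants") <- ensemble$variant[excluded]
  class(res) <- c("scenario_fractions", "data.frame")
  res
}

#' Stress-stratified apoptosis versus Beclin-1 expression
#'
#' Tabulates the apoptotic fraction by stress band and Beclin-1 expression
#' bin. Default bands are mild (0 < S <= 1), moderate (1 < S <= 2.5) and
#' severe (2.5 < S <= 5), plus an extreme band (5 < S <= 10) covering the
#' rest of the sampled stress range. Expression bins are log-spaced (the
#' sampled `alpha_B` spans almost two decades). Bins with fewer than
#' `min_count` variants are reported as missing (`NA` fraction), not zero.
#'
#' @param outcomes data.frame with columns `S`, `alpha_B` and a logical
#'   `apoptotic` (e.g. derived from the `outcomes` attribute of
#'   [scenario_fractions()]).
#' @param bands named list of `c(low, high]` stress intervals.
#' @param breaks `alpha_B` bin edges; default 5 log-spaced bins over the
#'   sampled range \[0.1, 5\].
#' @param min_count smallest bin occupancy reported as a fraction.
#' @return data.frame with `band`, `bin`, `alpha_B_mid`, `n`, `n_apoptotic`,
#'   `fraction`.
#' @export
stratified_apoptosis <- function(outcomes,
                                 bands = list(mild = c(0, 1),
                                              moderate = c(1, 2.5),
                                              severe = c(2.5, 5),
                                              extreme = c(5, 10)),
                                 breaks = exp(seq(log(0.1), log(5),
                                                  length.out = 6)),
                                 min_count = 5) {
  stopifnot(all(c("S", "alpha_B", "apoptotic") %in% names(outcomes)))
  rows <- list()
  mids <- sqrt(breaks[-length(breaks)] * breaks[-1])
  for (bn in names(bands)) {
    b <- bands[[bn]]
    sel <- outcomes$S > b[1] & outcomes$S <= b[2] & !is.na(outcomes$apoptotic)
    bin <- cut(outcomes$alpha_B[sel], breaks, include.lowest = TRUE,
               labels = FALSE)
    for (k in seq_len(length(breaks) - 1)) {
      idx <- which(bin == k)
      nk <- length(idx)
      ka <- sum(outcomes$apoptotic[sel][idx])
      rows[[length(rows) + 1]] <- data.frame(
        band = bn, bin = k, alpha_B_mid = mids[k], n = nk, n_apoptotic = ka,
        fraction = if (nk >= min_count) ka / nk else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Beclin-1 viability window at a given stress level
#'
#' Scans the Beclin-1 expression rate `alpha_B` over a grid, simulating each
#' value under the standard protocol (stress on \[0, 24\] h, 48 h horizon)
#' from its own resting state, and locates the survival interval
#' `(theta_L, theta_H)` — the minimum and maximum expression rates
#' compatible with survival — refining both boundaries by bisection.
#' Grid points whose resting state is degenerate (unbounded autophagosome
#' accumulation) are counted as non-surviving. A non-contiguous survival
#' set is an error (it would signal an unexpected regime) and reports the
#' survival mask.
#'
#' @param base a [beclin_params()] set; its `alpha_B` and `S` are overridden.
#' @param S stress level.
#' @param grid ascending `alpha_B` values (default 100 log-spaced points on
#'   \[0.1, 10\]); at least 50 points.
#' @param refine_tol bisection tolerance on the thresholds.
#' @param protocol protocol template (level replaced by `S`).
#' @param rtol,atol solver tolerances.
#' @return list of class `viability_window`: `S`, `theta_L`, `theta_H`,
#'   `empty`, plus the scan `grid` and `survival` mask.
#' @export
viability_window <- function(base, S,
                             grid = exp(seq(log(0.1), log(10),
                                            length.out = 100)),
                             refine_tol = 1e-3,
                             protocol = default_protocol(),
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(grid) >= 50, !is.unsorted(grid))
  proto <- stress_protocol(S, protocol$t_on, protocol$t_off, protocol$horizon)
  survives <- function(a) {
    p <- base; p$alpha_B <- a; p$S <- S
    ss <- unstressed_steady_state(p)
    if (ss$degenerate) return(FALSE)
    final_caspase(p, proto, ss$state, rtol = rtol, atol = atol) <= 0.5
  }
  mask <- vapply(grid, survives, logical(1))
  if (!any(mask))
    return(structure(list(S = S, theta_L = NA_real_, theta_H = NA_real_,
                          empty = TRUE, grid = grid, survival = mask),
                     class = "viability_window"))
  runs <- rle(mask)
  if (sum(runs$values) > 1)
    stop("non-contiguous survival set over alpha_B; mask: ",
         paste(as.integer(mask), collapse = ""))
  idx <- which(mask)
  lo_i <- min(idx); hi_i <- max(idx)
  bisect <- function(a_bad, a_good) {
    while (abs(a_good - a_bad) > refine_tol) {
      mid <- (a_bad + a_good) / 2
      if (survives(mid)) a_good <- mid else a_bad <- mid
    }
    (a_bad + a_good) / 2
  }
  theta_L <- if (lo_i == 1) grid[1] else bisect(grid[lo_i - 1], grid[lo_i])
  theta_H <- if (hi_i == length(grid)) grid[length(grid)]
             else bisect(grid[hi_i + 1], grid[hi_i])
  structure(list(S = S, theta_L = theta_L, theta_H = theta_H, empty = FALSE,
                 grid = grid, survival = mask),
            class = "viability_window")
}

#' @export
print.viability_window <- function(x, ...) {
  if (x$empty)
    cat(sprintf("<viability_window> S = %g: empty (no surviving alpha_B)\n",
                x$S))
  else
    cat(sprintf("<viability_window> S = %g: theta_L = %.3f, theta_H = %.3f\n",
                x$S, x$theta_L, x$theta_H))
  invisible(x)
}

#' In-silico Beclin-1 knockdown / overexpression experiment
#'
#' Simulates noise-perturbed populations ([perturbed_population()]) whose
#' basal Beclin-1 expression is scaled by each fold (0.5 = knockdown,
#' 2 = overexpression) at a given stress, and reports the apoptotic
#' fraction per fold. Every cell starts from the resting state of the
#' untreated base variant, with its perturbed expression rate acting from
#' stress onset — the in-silico analogue of transfecting resting cells and
#' then applying the insult. This also keeps cells whose expression is
#' truncated to zero (they cannot rest on their own, but their fate under
#' the perturbation is well defined).
#'
#' @param base a [beclin_params()] set (reference cell).
#' @param S stress level.
#' @param folds expression multipliers.
#' @param n population size per fold.
#' @param noise_sd Gaussian noise SD added to the scaled expression rate.
#' @param seed RNG seed.
#' @param protocol protocol template.
#' @param rtol,atol solver tolerances.
#' @return data.frame with `fold`, `n`, `n_apoptotic`, `fraction`,
#'   `ci_lo`, `ci_hi`.
#' @export
perturbation_experiment <- function(base, S, folds = c(0.5, 1, 2), n = 1000,
                                    noise_sd = 0.5, seed = 1,
                                    protocol = default_protocol(),
                                    rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(folds > 0))
  ss <- unstressed_steady_state(base)
  if (ss$degenerate) stop("degenerate base variant: ", ss$reason)
  proto <- stress_protocol(S, protocol$t_on, protocol$t_off, protocol$horizon)
  res <- lapply(seq_along(folds), function(fi) {
    pop <- perturbed_population(base, folds[fi], n, noise_sd = noise_sd,
                                seed = seed + fi - 1)
    ap <- vapply(pop$alpha_B, function(a) {
      p <- base; p$alpha_B <- a; p$S <- S
      final_caspase(p, proto, ss$state, rtol = rtol, atol = atol) > 0.5
    }, logical(1))
    k <- sum(ap)
    ci <- proportion_ci(k, n)
    data.frame(fold = folds[fi], n = n, n_apoptotic = k, fraction = k / n,
               ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Local sensitivity of the viability thresholds
#'
#' Recomputes the viability window after multiplying one parameter at a
#' time by `fold`, and reports the resulting shifts of the lower and upper
#' Beclin-1 thresholds.
#'
#' @param base a [beclin_params()] set.
#' @param S stress level.
#' @param fold multiplicative perturbation applied to each parameter in turn.
#' @param parameters which parameters to perturb (default: all sampled rate
#'   parameters except the expression rate being scanned).
#' @param ... passed to [viability_window()].
#' @return data.frame with `parameter`, `theta_L`, `theta_H`, `d_theta_L`,
#'   `d_theta_H`, `empty`; attribute `reference` holds the unperturbed
#'   window.
#' @export
local_sensitivity <- function(base, S, fold = 2,
                              parameters = setdiff(names(sampling_ranges()),
                                                   c("S", "alpha_B")),
                              ...) {
  stopifnot(fold > 0)
  ref <- viability_window(base, S, ...)
  rows <- lapply(parameters, function(nm) {
    p <- base; p[[nm]] <- p[[nm]] * fold
    w <- viability_window(p, S, ...)
    data.frame(parameter = nm, theta_L = w$theta_L, theta_H = w$theta_H,
               d_theta_L = w$theta_L - ref$theta_L,
               d_theta_H = w$theta_H - ref$theta_H, empty = w$empty)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "reference") <- ref
  out
}

#' Golden-hour stress-duration threshold
#'
#' Finds the minimal ischemic-stress duration `T*` that commits the cell to
#' apoptosis: stress `S` is applied on `[0, d]` of a 48 h simulation and the
#' boundary of the 48-h apoptosis classification is located by bisection on
#' `d`. Commitment is monotone in duration (the switch is bistable), which
#' the bisection bracket maintains by construction.
#'
#' If even stress sustained for the whole horizon does not commit the cell,
#' the threshold is censored at the horizon: `t_star = horizon` with
#' `unbounded = TRUE` (the golden hour exceeds the observable window).
#'
#' @param params a [beclin_params()] set (interventions applied).
#' @param S stress level.
#' @param resolution bisection resolution on the duration (h), at most 0.1.
#' @param horizon total simulated time (h).
#' @param init initial state; default the resting state of `params`. For
#'   intervention runs pass the resting state of the untreated base so the
#'   treatment acts from stress onset on an untreated cell.
#' @param rtol,atol solver tolerances.
#' @return list of class `golden_hour`: `t_star` (h), `unbounded`,
#'   `S`, `resolution`, `horizon`.
#' @export
duration_threshold <- function(params, S, resolution = 0.05, horizon = 48,
                               init = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(resolution <= 0.1, resolution > 0, S >= 0)
  if (is.null(init)) {
    ss <- unstressed_steady_state(params)
    if (ss$degenerate) stop("degenerate variant: ", ss$reason)
    init <- ss$state
  }
  committed <- function(d) {
    proto <- stress_protocol(S, 0, d, horizon)
    final_caspase(params, proto, init, rtol = rtol, atol = atol) > 0.5
  }
  if (committed(0))
    return(structure(list(t_star = 0, unbounded = FALSE, S = S,
                          resolution = resolution, horizon = horizon),
                     class = "golden_hour"))
  if (!committed(horizon))
    return(structure(list(t_star = horizon, unbounded = TRUE, S = S,
                          resolution = resolution, horizon = horizon),
                     class = "golden_hour"))
  lo <- 0; hi <- horizon
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    if (committed(mid)) hi <- mid else lo <- mid
  }
  structure(list(t_star = (lo + hi) / 2, unbounded = FALSE, S = S,
                 resolution = resolution, horizon = horizon),
            class = "golden_hour")
}

#' @export
print.golden_hour <- function(x, ...) {
  cat(sprintf("<golden_hour> S = %g: T* = %.2f h%s\n", x$S, x$t_star,
              if (x$unbounded) " (censored at horizon)" else ""))
  invisible(x)
}

#' Golden-hour intervention panel
#'
#' Duration thresholds and fold-extensions for candidate neuroprotective
#' interventions at severe stress, relative to the untreated baseline:
#' halving Beclin-1 expression (`alpha_B` x 0.5), eliminating
#' Caspase-mediated Beclin-1 cleavage (`beta_B = 0`), enhancing autophagic
#' flux five-fold (`beta_A` x 5), abolishing autophagosome-mediated Caspase
#' activation (`sigma_C = 0`), and reducing autophagic IAP degradation
#' ten-fold (`sigma_J` x 0.1); each intervention is additionally combined
#' with a ten-fold higher flux saturation threshold (`phi_A` x 10).
#'
#' All runs start from the baseline variant's resting state, with the
#' intervention acting from stress onset (a treatment applied to an
#' untreated resting cell). Censored thresholds (no commitment within the
#' horizon) are reported at the horizon with `censored = TRUE`; their folds
#' are lower bounds.
#'
#' @param base a [beclin_params()] set; default the representative variant.
#' @param S stress level (default 8, the severe-stress calibration).
#' @param resolution bisection resolution (h).
#' @param horizon simulation horizon (h).
#' @param rtol,atol solver tolerances.
#' @return data.frame with `intervention`, `overrides`, `raise_phi_A`,
#'   `t_star`, `fold`, `censored`.
#' @export
intervention_panel <- function(base = r_variant(), S = 8, resolution = 0.05,
                               horizon = 48, rtol = 1e-8, atol = 1e-10) {
  ss <- unstressed_steady_state(base)
  if (ss$degenerate) stop("degenerate base variant")
  init <- ss$state
  mods <- list(
    "halve-expression"   = list(alpha_B = 0.5 * base$alpha_B),
    "no-cleavage"        = list(beta_B = 0),
    "flux-5x"            = list(beta_A = 5 * base$beta_A),
    "no-autophagosome-activation" = list(sigma_C = 0),
    "iap-sparing-10x"    = list(sigma_J = 0.1 * base$sigma_J)
  )
  run <- function(ov, raise) {
    p <- base
    for (nm in names(ov)) p[[nm]] <- ov[[nm]]
    if (raise) p$phi_A <- 10 * base$phi_A
    duration_threshold(p, S, resolution = resolution, horizon = horizon,
                       init = init, rtol = rtol, atol = atol)
  }
  base_gh <- run(list(), FALSE)
  rows <- list(data.frame(intervention = "baseline", overrides = "",
                          raise_phi_A = FALSE, t_star = base_gh$t_star,
                          fold = 1, censored = base_gh$unbounded))
  for (nm in names(mods)) {
    for (raise in c(FALSE, TRUE)) {
      gh <- run(mods[[nm]], raise)
      rows[[length(rows) + 1]] <- data.frame(
        intervention = nm,
        overrides = paste(names(mods[[nm]]),
                          signif(unlist(mods[[nm]]), 4),
                          sep = "=", collapse = ";"),
        raise_phi_A = raise, t_star = gh$t_star,
        fold = gh$t_star / base_gh$t_star, censored = gh$unbounded)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
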
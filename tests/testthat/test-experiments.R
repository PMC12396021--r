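# Pipeline experiments: scenario fractions, stratification, viability
# windows, perturbation populations, sensitivity, duration thresholds.

test_that("without stress only basin-less variants die", {
  ens <- small_ensemble()[1:60, ]
  sf <- scenario_fractions(ens, list(scenario_spec("rest", c(S = 0))))
  out <- attr(sf, "outcomes")
  kept <- !out$excluded
  doomed <- vapply(which(kept), function(i) {
    ss <- unstressed_steady_state(row_params(ens, i))
    !isTRUE(ss$survival_basin)
  }, logical(1))
  expect_equal(out$rest[kept], doomed)
})

test_that("scenario fractions are paired and exclusion sets shared", {
  ens <- small_ensemble()[1:120, ]
  sf <- scenario_fractions(ens, canonical_scenarios()[c(
    "wild-type", "no-mech1", "no-saturation")])
  expect_equal(length(unique(sf$n)), 1)
  out <- attr(sf, "outcomes")
  expect_true(all(is.na(out[out$excluded, "wild-type"]) |
                    !out$excluded[out$excluded]))
  # knockout can only rescue, up to a small noise allowance
  kept <- !out$excluded
  flips_bad <- sum(out[kept, "no-mech1"] & !out[kept, "wild-type"])
  expect_lt(flips_bad / sum(kept), 0.01)
  # confidence bounds bracket the fractions
  expect_true(all(sf$ci_lo <= sf$fraction & sf$fraction <= sf$ci_hi))
})

test_that("stratified tables flag thin bins and handle degenerate input", {
  out <- data.frame(S = c(0.5, 0.5, 3), alpha_B = c(0.2, 1, 1),
                    apoptotic = c(TRUE, FALSE, TRUE))
  tab <- stratified_apoptosis(out, min_count = 1)
  expect_true(all(tab$fraction[tab$n > 0] %in% c(0, 1)))
  expect_true(all(is.na(tab$fraction[tab$n == 0])))
  tab2 <- stratified_apoptosis(out, min_count = 2)
  expect_true(all(is.na(tab2$fraction)))
  expect_equal(sum(tab$n), 3)
})

test_that("the viability window narrows from above with stress", {
  rv <- r_variant()
  grid <- exp(seq(log(0.1), log(10), length.out = 60))
  w_lo <- viability_window(rv, 0.5, grid = grid)
  w_hi <- viability_window(rv, 2, grid = grid)
  expect_false(w_lo$empty || w_hi$empty)
  expect_lt(w_lo$theta_L, w_lo$theta_H)
  expect_lt(w_hi$theta_H, w_lo$theta_H)
  # sustained severe stress leaves no viable expression rate
  w8 <- viability_window(rv, 8, grid = grid)
  expect_true(w8$empty)
  expect_true(is.na(w8$theta_L))
})

test_that("inefficient autophagosome formation makes Beclin-1 purely protective", {
  # with alpha_A halved, survival under moderate stress requires high
  # expression (or is impossible): no upper threshold below the grid top
  p <- beclin_params(alpha_A = 0.5)
  w <- viability_window(p, 2, grid = exp(seq(log(0.1), log(10),
                                             length.out = 60)))
  # survival, where possible at all, only at the high-expression end:
  # the survival mask is monotone nondecreasing in alpha_B
  expect_true(all(diff(w$survival) >= 0))
  if (!w$empty) expect_equal(w$theta_H, 10, tolerance = 1e-6)
})

test_that("perturbation experiment is deterministic in the zero-noise limit", {
  rv <- r_variant()
  pe <- perturbation_experiment(rv, 0.5, folds = 1, n = 3, noise_sd = 0)
  expect_true(pe$fraction %in% c(0, 1))
  pe2 <- perturbation_experiment(rv, 8, folds = 1, n = 3, noise_sd = 0)
  expect_equal(pe2$fraction, 1)
})

test_that("sensitivity shifts vanish at the identity perturbation", {
  rv <- r_variant()
  grid <- exp(seq(log(0.1), log(10), length.out = 50))
  sens <- local_sensitivity(rv, 2, fold = 1,
                            parameters = c("beta_B", "alpha_A"), grid = grid)
  expect_equal(sens$d_theta_L, c(0, 0), tolerance = 2e-3)
  expect_equal(sens$d_theta_H, c(0, 0), tolerance = 2e-3)
})

test_that("cleavage and autophagosome-formation rates move both thresholds", {
  rv <- r_variant()
  grid <- exp(seq(log(0.1), log(10), length.out = 50))
  sens <- local_sensitivity(rv, 2, fold = 0.5, parameters = "beta_B",
                            grid = grid)
  expect_gt(abs(sens$d_theta_L), 5e-3)
  expect_gt(abs(sens$d_theta_H), 5e-3)
  # a milder formation deficit shifts both thresholds; halving it is so
  # severe that moderate stress leaves no viable expression rate at all
  sens8 <- local_sensitivity(rv, 2, fold = 0.8, parameters = "alpha_A",
                             grid = grid)
  expect_gt(abs(sens8$d_theta_L), 5e-3)
  expect_gt(abs(sens8$d_theta_H), 5e-3)
  sens5 <- local_sensitivity(rv, 2, fold = 0.5, parameters = "alpha_A",
                             grid = grid)
  expect_true(sens5$empty)
})

test_that("commitment is a single switch in stress duration", {
  rv <- r_variant()
  ss <- unstressed_steady_state(rv)
  outcome <- vapply(seq(0, 10, by = 0.1), function(d) {
    proto <- stress_protocol(8, 0, d, 48)
    tr <- simulate_cell(rv, proto, init = ss$state)
    classify_apoptosis(tr)
  }, logical(1))
  expect_equal(sum(diff(outcome) != 0), 1)
  expect_false(outcome[1])
  expect_true(outcome[length(outcome)])
})

test_that("duration thresholds detect unbounded golden hours", {
  rv <- r_variant()
  gh0 <- duration_threshold(rv, S = 0, resolution = 0.1)
  expect_true(gh0$unbounded)
  expect_equal(gh0$t_star, gh0$horizon)
  gh8 <- duration_threshold(rv, S = 8)
  expect_false(gh8$unbounded)
  expect_gt(gh8$t_star, 4)
  expect_lt(gh8$t_star, 5.5)
  expect_error(duration_threshold(rv, S = 8, resolution = 0.2), "resolution")
})

test_that("intervention folds are stable under a finer bisection", {
  panel1 <- intervention_panel(S = 8, resolution = 0.05)
  panel2 <- intervention_panel(S = 8, resolution = 0.025)
  free <- !panel1$censored
  expect_true(all(abs(panel1$fold[free] - panel2$fold[free]) < 0.05))
  expect_equal(panel1$fold[panel1$intervention == "baseline"], 1)
  # interventions only lengthen the golden hour
  expect_true(all(panel1$fold >= 1 - 1e-9))
})
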
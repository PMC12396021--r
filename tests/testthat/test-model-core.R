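# Core model: right-hand side algebra, resting states, integration,
# classification.

test_that("rhs reproduces the algebraic resting balance of the R variant", {
  p <- r_variant()
  rest <- stress_protocol(0, 0, 0, 48)
  # with C = 0 the first five equations balance at (1, 0, 10/9, 1)
  d <- beclin_rhs(c(B = 1, Bc = 0, A = 10 / 9, M = 1, C = 0), 0, p, rest)
  expect_equal(unname(d[c("B", "Bc", "A", "M")]), rep(0, 4), tolerance = 1e-12)
  expect_equal(attr(d, "flux"), 1, tolerance = 1e-12)
  # the Caspase equation is driven positive by the mitochondrial term
  expect_gt(d[["C"]], 0)
})

test_that("rhs boundary behaviour: empty cell, full Caspase, negative states", {
  p <- r_variant()
  rest <- stress_protocol(0, 0, 0, 48)
  d0 <- beclin_rhs(c(B = 0, Bc = 0, A = 0, M = 0, C = 0), 0, p, rest)
  expect_equal(as.numeric(d0), c(p$alpha_B, 0, 0, p$alpha_M, 0),
               tolerance = 1e-14)
  # C = 1 kills the activation term, so C can never exceed 1
  d1 <- beclin_rhs(c(B = 1, Bc = 0, A = 1, M = 5, C = 1), 0, p, rest)
  expect_lt(d1[["C"]], 0)
  expect_error(
    beclin_rhs(c(B = -0.1, Bc = 0, A = 1, M = 1, C = 0), 0, p, rest),
    "negative")
})

test_that("stress protocol gates the stress-dependent production terms", {
  p <- r_variant()
  proto <- stress_protocol(4, t_on = 2, t_off = 10, horizon = 48)
  expect_equal(stress_at(proto, c(0, 2, 5, 10, 20)), c(0, 4, 4, 0, 0))
  s <- c(B = 1, Bc = 0, A = 10 / 9, M = 1, C = 0)
  d_on <- beclin_rhs(s, 5, p, proto)
  expect_equal(d_on[["B"]], p$alpha_B * p$u_B * 4, tolerance = 1e-12)
  expect_equal(d_on[["M"]], p$alpha_M * p$u_M * 4, tolerance = 1e-12)
})

test_that("unstressed steady state is a genuine equilibrium on the survival branch", {
  p <- r_variant()
  ss <- unstressed_steady_state(p)
  expect_false(ss$degenerate)
  expect_true(ss$survival_basin)
  rest <- stress_protocol(0, 0, 0, 48)
  expect_lt(max(abs(beclin_rhs(ss$state, 0, p, rest))), 1e-8)
  expect_lt(ss$state[["C"]], 0.05)
  # relaxation oracle: integrating the unstressed system from a nearby
  # state returns to the same equilibrium
  tr <- simulate_cell(p, stress_protocol(0, 0, 0, 400),
                      init = ss$state * c(1.1, 1, 0.9, 1.2, 1),
                      times = c(0, 400))
  expect_equal(unlist(tr[2, c("B", "Bc", "A", "M", "C")]), ss$state,
               tolerance = 1e-6)
})

test_that("resting Beclin-1 approaches alpha_B/gamma_B when Caspase is low", {
  p <- beclin_params(alpha_B = 2)
  ss <- unstressed_steady_state(p)
  expect_equal(ss$state[["B"]], 2, tolerance = 0.05)
})

test_that("flux-saturated variants are flagged degenerate", {
  # alpha_A * (alpha_B/gamma_B) = 20 exceeds beta_A * phi_A = 2.5
  p <- beclin_params(alpha_B = 5, gamma_B = 0.5, alpha_A = 2,
                     beta_A = 0.5, phi_A = 5)
  ss <- unstressed_steady_state(p)
  expect_true(ss$degenerate)
  expect_match(ss$reason, "saturated")
  expect_error(simulate_cell(p, stress_protocol(1)), "degenerate")
})

test_that("simulation from the resting state is invariant without stress", {
  p <- r_variant()
  ss <- unstressed_steady_state(p)
  tr <- simulate_cell(p, stress_protocol(0, 0, 0, 48), init = ss$state,
                      times = seq(0, 48, by = 4))
  for (v in c("B", "Bc", "A", "M", "C"))
    expect_lt(max(abs(tr[[v]] - ss$state[[v]])), 1e-6)
})

test_that("severe stress commits the R variant only beyond the duration threshold", {
  p <- r_variant()
  ss <- unstressed_steady_state(p)
  long <- simulate_cell(p, stress_protocol(8, 0, 24, 48), init = ss$state)
  short <- simulate_cell(p, stress_protocol(8, 0, 2, 48), init = ss$state)
  expect_true(classify_apoptosis(long))
  expect_false(classify_apoptosis(short))
})

test_that("apoptosis classification is strict at the threshold", {
  tr <- data.frame(time = c(0, 48), B = 1, Bc = 0, A = 1, M = 1,
                   C = c(0.1, 0.5), J = 1)
  class(tr) <- c("beclin_trajectory", "data.frame")
  expect_false(classify_apoptosis(tr))
  tr$C[2] <- 0.5 + 1e-9
  expect_true(classify_apoptosis(tr))
  tr$C[2] <- 0.94
  expect_true(classify_apoptosis(tr))
  tr$C[2] <- 0.02
  expect_false(classify_apoptosis(tr))
  expect_error(classify_apoptosis(tr, at = 100), "outside")
})

test_that("autophagic flux saturates at beta_A * phi_A", {
  p <- r_variant()
  A <- exp(seq(log(1e-3), log(1e4), length.out = 200))
  J <- autophagic_flux(A, p)
  expect_true(all(diff(J) > 0))
  expect_true(all(J < p$beta_A * p$phi_A))
  expect_gt(autophagic_flux(1e9 * p$phi_A, p) / (p$beta_A * p$phi_A), 0.999)
})

test_that("quasi-steady mitochondrial load is nondecreasing in stress", {
  # Caspase feedback silenced so M reflects the damage/mitophagy balance
  p <- beclin_params(alpha_C = 0, sigma_C = 0)
  ss <- unstressed_steady_state(p)
  M24 <- vapply(0:10, function(S) {
    tr <- simulate_cell(p, stress_protocol(S, 0, 24, 24), init = ss$state,
                        times = c(0, 24))
    tr$M[2]
  }, numeric(1))
  expect_true(all(diff(M24) > -1e-6))
})

test_that("trajectories of random variants stay inside the state box", {
  ens <- small_ensemble()
  grid <- seq(0, 48, by = 2)
  checked <- 0
  for (i in seq_len(nrow(ens))) {
    p <- row_params(ens, i)
    ss <- unstressed_steady_state(p)
    if (ss$degenerate) next
    tr <- simulate_cell(p, stress_protocol(p$S, 0, 24, 48), init = ss$state,
                        times = grid)
    expect_gte(min(tr$B, tr$Bc, tr$A, tr$M, tr$C), 0)
    expect_lte(max(tr$C), 1)
    checked <- checked + 1
  }
  expect_gte(checked, 150)
})

test_that("halving the solver tolerances leaves the 48-h outcome unchanged", {
  ens <- small_ensemble()
  set.seed(7)
  idx <- sample(which(!vapply(seq_len(nrow(ens)), function(i)
    unstressed_steady_state(row_params(ens, i))$degenerate, logical(1))), 50)
  for (i in idx) {
    p <- row_params(ens, i)
    c1 <- run_variant(p, rtol = 1e-8, atol = 1e-10)
    c2 <- run_variant(p, rtol = 5e-9, atol = 5e-11)
    expect_lt(abs(c1 - c2), 1e-4)
    if (abs(c1 - 0.5) > 1e-3) expect_identical(c1 > 0.5, c2 > 0.5)
  }
})

test_that("adaptive integration matches a fixed-step RK4 oracle", {
  ens <- small_ensemble()
  set.seed(11)
  idx <- sample(which(!vapply(seq_len(nrow(ens)), function(i)
    unstressed_steady_state(row_params(ens, i))$degenerate, logical(1))), 10)
  for (i in idx) {
    p <- row_params(ens, i)
    ss <- unstressed_steady_state(p)
    proto <- stress_protocol(p$S, 0, 24, 48)
    ad <- simulate_cell(p, proto, init = ss$state, times = c(0, 24, 48))
    rk <- simulate_cell(p, proto, init = ss$state,
                        times = seq(0, 48, by = 1e-3), method = "rk4")
    rk <- rk[rk$time %in% c(0, 24, 48), ]
    for (v in c("B", "Bc", "A", "M", "C"))
      expect_lt(max(abs(ad[[v]] - rk[[v]])), 1e-3)
  }
})

test_that("the compiled derivative agrees with the R-level right-hand side", {
  p <- r_variant()
  proto <- stress_protocol(6, 0, 24, 48)
  ss <- unstressed_steady_state(p)
  tc <- simulate_cell(p, proto, init = ss$state, times = seq(0, 48, 6),
                      compiled = TRUE)
  tr <- simulate_cell(p, proto, init = ss$state, times = seq(0, 48, 6),
                      compiled = FALSE)
  for (v in c("B", "Bc", "A", "M", "C", "J"))
    expect_equal(tc[[v]], tr[[v]], tolerance = 1e-6)
})

test_that("parameter files and trajectories round-trip through disk", {
  p <- beclin_params(alpha_B = 2.5, sigma_M = 37.5)
  f <- tempfile(fileext = ".json")
  write_params(p, f)
  expect_equal(unclass(read_params(f)), unclass(p), tolerance = 1e-12)
  tr <- simulate_cell(r_variant(), stress_protocol(2), times = seq(0, 48, 12))
  g <- tempfile(fileext = ".csv")
  write_trajectory(tr, g)
  tr2 <- read_trajectory(g)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-12)
})
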
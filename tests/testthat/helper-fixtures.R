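# Shared fixtures for the test suite. Everything is generated in code with
# fixed seeds; nothing is read from disk.

# a small paired ensemble reused by several model/experiment tests
small_ensemble <- local({
  memo <- NULL
  function(n = 200, seed = 42) {
    if (is.null(memo)) memo <<- sample_ensemble(n, seed = seed)
    memo
  }
})

# params object for row i of an ensemble data.frame
row_params <- function(ens, i) {
  cols <- c("S", "alpha_B", "beta_B", "gamma_B", "gamma_BC", "alpha_A",
            "beta_A", "phi_A", "alpha_M", "sigma_M", "gamma_M", "alpha_C",
            "sigma_C", "mu_C", "gamma_C", "phi_C", "sigma_J", "u_B", "u_M")
  do.call(beclin_params, as.list(ens[i, cols]))
}

# final-state shortcut: C at the horizon under the standard 0-24 h stress
run_variant <- function(p, S = p$S, t_off = 24, horizon = 48, ...) {
  ss <- unstressed_steady_state(p)
  if (ss$degenerate) return(NA_real_)
  tr <- simulate_cell(p, stress_protocol(S, 0, t_off, horizon),
                      init = ss$state, ...)
  tr$C[nrow(tr)]
}
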
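# Core ODE model: right-hand side, resting states, simulation, classification.

#' Saturable autophagic flux
#'
#' `J(A) = beta_A * A / (1 + A / phi_A)`: linear in the autophagosome pool at
#' low abundance, saturating at `beta_A * phi_A` when lysosomal capacity is
#' exhausted (`A >> phi_A`).
#'
#' @param A autophagosome abundance (vectorised).
#' @param params a [beclin_params()] set.
#' @return flux J (1/h units of autophagosome clearance).
#' @export
autophagic_flux <- function(A, params) {
  params$beta_A * A / (1 + A / params$phi_A)
}

#' Model right-hand side
#'
#' Time derivatives of the five states (B, Bc, A, M, C) at a given time under
#' a stress protocol. This is the reference R implementation; numerical
#' integration uses the equivalent compiled version (see [simulate_cell()]).
#'
#' The Caspase-3 equation combines a saturable activation term
#' `(alpha_C*M + sigma_C*A + mu_C*C/(phi_C + 1 - C)) * (1 - C)` with an
#' IAP-mediated inactivation term `gamma_C*C / (phi_C + sigma_J*J + C)`;
#' the shared saturation of both gives zero-order ultrasensitivity and a
#' switch-like response.
#'
#' @param state named numeric vector `c(B, Bc, A, M, C)`; components must be
#'   nonnegative and `C <= 1` (tiny negative solver noise below `neg_tol` is
#'   clipped; larger violations are an error).
#' @param t time (h).
#' @param params a [beclin_params()] set.
#' @param protocol a [stress_protocol()]; stress at `t` is taken from it.
#' @param neg_tol magnitude below which negative components are treated as
#'   roundoff and clipped to zero.
#' @return named vector of derivatives `c(B, Bc, A, M, C)` with attribute
#'   `flux` holding J.
#' @examples
#' p <- r_variant()
#' beclin_rhs(c(B = 1, Bc = 0, A = 10 / 9, M = 1, C = 0), 0, p,
#'            stress_protocol(0))
#' @export
beclin_rhs <- function(state, t, params, protocol, neg_tol = 1e-8) {
  if (any(state < -neg_tol))
    stop("negative state component(s): ",
         paste(names(state)[state < -neg_tol], collapse = ", "))
  state <- pmax(state, 0)
  S <- stress_at(protocol, t)
  B <- state[["B"]]; Bc <- state[["Bc"]]; A <- state[["A"]]
  M <- state[["M"]]; C <- state[["C"]]
  J <- autophagic_flux(A, params)
  d <- c(
    B  = params$alpha_B * (1 + params$u_B * S) -
         params$beta_B * C * B - params$gamma_B * B,
    Bc = params$beta_B * C * B - params$gamma_BC * Bc,
    A  = params$alpha_A * B - J,
    M  = params$alpha_M * (1 + params$u_M * S) + params$sigma_M * Bc -
         params$gamma_M * J * M,
    C  = (params$alpha_C * M + params$sigma_C * A +
            params$mu_C * C / (params$phi_C + 1 - C)) * (1 - C) -
         params$gamma_C * C / (params$phi_C + params$sigma_J * J + C)
  )
  attr(d, "flux") <- J
  d
}

#' Unstressed resting state of a variant
#'
#' Solves the S = 0 steady state by fixed-point iteration on the Caspase
#' level: given C, the remaining states have closed forms
#' (`B = alpha_B / (beta_B*C + gamma_B)`, A from the flux balance
#' `alpha_A*B = J(A)`, `Bc = beta_B*C*B/gamma_BC`,
#' `M = (alpha_M + sigma_M*Bc) / (gamma_M*J)`), and C is updated to the
#' lowest stable root of the Caspase balance with the frozen drives
#' `alpha1 = alpha_C*M + sigma_C*A`, `alpha2 = sigma_J*J`.
#'
#' Two qualitatively different outcomes are flagged:
#' * `degenerate = TRUE` ("flux-saturated at rest"): no finite autophagosome
#'   steady state exists because `alpha_A*B >= beta_A*phi_A` (formation
#'   exceeds the flux supremum). Such variants have no resting balance at
#'   all and are excluded from ensemble runs (counts reported).
#' * `survival_basin = FALSE`: a resting state exists but its lowest stable
#'   Caspase root is on the apoptotic branch (C > 0.5); the cleavage feedback
#'   loop C -> Bc -> M destroys the survival state. These variants are
#'   intrinsically doomed cells; they are kept and simulated from their
#'   (apoptotic) resting state.
#'
#' @param params a [beclin_params()] set.
#' @param tol convergence tolerance on C between fixed-point iterations.
#' @param max_iter maximum fixed-point iterations.
#' @param residual_tol largest acceptable per-component magnitude of the
#'   model right-hand side at the returned state.
#' @return a list with `state` (named vector B, Bc, A, M, C or NULL),
#'   `degenerate`, `survival_basin`, and `reason` (for degenerate variants).
#' @export
unstressed_steady_state <- function(params, tol = 1e-12, max_iter = 200,
                                    residual_tol = 1e-8) {
  resolve <- function(C) {
    B <- params$alpha_B / (params$beta_B * C + params$gamma_B)
    J <- params$alpha_A * B
    if (J <= 0)
      return(list(degenerate = TRUE,
                  reason = "no resting autophagic flux (mitophagy balance impossible)"))
    if (J >= params$beta_A * params$phi_A)
      return(list(degenerate = TRUE,
                  reason = "flux saturated at rest (alpha_A*B >= beta_A*phi_A)"))
    A <- J / (params$beta_A - J / params$phi_A)
    Bc <- params$beta_B * C * B / params$gamma_BC
    M <- (params$alpha_M + params$sigma_M * Bc) / (params$gamma_M * J)
    list(degenerate = FALSE, B = B, Bc = Bc, A = A, M = M, J = J)
  }
  C <- 0
  st <- NULL
  for (it in seq_len(max_iter)) {
    st <- resolve(C)
    if (st$degenerate)
      return(list(state = NULL, degenerate = TRUE, survival_basin = NA,
                  reason = st$reason))
    sp <- switch_params(mu_C = params$mu_C, gamma_C = params$gamma_C,
                        phi_C = params$phi_C,
                        alpha1 = params$alpha_C * st$M + params$sigma_C * st$A,
                        alpha2 = params$sigma_J * st$J)
    cp <- caspase_critical_points(sp)
    stable <- cp$C[cp$stability == "stable"]
    if (!length(stable))
      return(list(state = NULL, degenerate = TRUE, survival_basin = NA,
                  reason = "no stable Caspase root at rest"))
    C_new <- min(stable)
    done <- abs(C_new - C) < tol
    C <- C_new
    if (done) break
  }
  st <- resolve(C)
  state <- c(B = st$B, Bc = st$Bc, A = st$A, M = st$M, C = C)
  rest <- stress_protocol(0, 0, 0, 0)
  res <- beclin_rhs(state, 0, params, rest)
  # near the resting saddle-node the fixed-point map can cycle between the
  # merging branches; finish those variants by relaxation integration
  chunk <- 0
  while (max(abs(res)) > residual_tol && chunk < 8) {
    relax <- stress_protocol(0, 0, 0, 500)
    tr <- simulate_cell(params, relax, init = pmin(pmax(state, 0),
                                                   c(Inf, Inf, Inf, Inf, 1)),
                        times = c(0, 500))
    state <- unlist(tr[nrow(tr), c("B", "Bc", "A", "M", "C")])
    res <- beclin_rhs(state, 0, params, rest)
    chunk <- chunk + 1
  }
  if (max(abs(res)) > residual_tol)
    stop("steady-state residual above tolerance: ", format(max(abs(res))))
  list(state = state, degenerate = FALSE, survival_basin = C <= 0.5,
       reason = NA_character_)
}

#' Simulate the model under a stress protocol
#'
#' Integrates the five-state system with a stiff-capable adaptive solver
#' (deSolve's `lsoda`, via the package's compiled derivative function).
#' The integration is restarted at the stress onset/offset so the solver
#' never steps across the discontinuity.
#'
#' @param params a [beclin_params()] set.
#' @param protocol a [stress_protocol()]; its `level` overrides `params$S`.
#' @param init named initial state `c(B, Bc, A, M, C)`; default is the
#'   variant's [unstressed_steady_state()] (an error for degenerate variants).
#' @param times output time grid within `[0, horizon]`; default is the
#'   protocol's break points plus the horizon (`c(0, t_on, t_off, horizon)`).
#'   Internal solver steps are unaffected by the output grid.
#' @param rtol,atol relative/absolute solver tolerances.
#' @param compiled use the compiled derivative function (the default); set
#'   `FALSE` to integrate through the R-level [beclin_rhs()] instead.
#' @param method integration method passed to [deSolve::ode()].
#' @param box_tol allowed violation of the state box (components below
#'   `-box_tol`, or C above `1 + box_tol`, abort with an error).
#' @return a `beclin_trajectory`: data.frame with columns
#'   `time, B, Bc, A, M, C, J`.
#' @examples
#' tr <- simulate_cell(r_variant(), stress_protocol(level = 8, t_off = 24))
#' classify_apoptosis(tr)
#' @export
simulate_cell <- function(params, protocol, init = NULL, times = NULL,
                          rtol = 1e-8, atol = 1e-10, compiled = TRUE,
                          method = "lsoda", box_tol = 1e-6) {
  validate_params(params)
  if (is.null(init)) {
    ss <- unstressed_steady_state(params)
    if (ss$degenerate)
      stop("variant is degenerate (", ss$reason,
           "); supply an explicit initial state")
    init <- ss$state
  }
  if (!all(c("B", "Bc", "A", "M", "C") %in% names(init)))
    stop("init must have components B, Bc, A, M, C")
  init <- init[c("B", "Bc", "A", "M", "C")]
  if (any(init < 0) || init[["C"]] > 1)
    stop("initial state outside the valid box")
  if (is.null(times))
    times <- unique(sort(c(0, protocol$t_on, protocol$t_off, protocol$horizon)))
  if (min(times) < 0 || max(times) > protocol$horizon)
    stop("output times must lie within [0, horizon]")
  breaks <- unique(sort(c(min(times), protocol$t_on, protocol$t_off, max(times))))
  breaks <- breaks[breaks >= min(times) & breaks <= max(times)]

  rows <- list()
  y <- init
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    if (t1 <= t0) next
    seg_times <- unique(sort(c(t0, times[times > t0 & times < t1], t1)))
    S_seg <- stress_at(protocol, (t0 + t1) / 2)
    if (compiled) {
      out <- deSolve::ode(
        y = y, times = seg_times, func = "beclin_derivs",
        parms = par_vector(params, S = S_seg),
        dllname = "beclinduality", initfunc = "beclin_initmod",
        nout = 1, outnames = "J",
        rtol = rtol, atol = atol, method = method
      )
    } else {
      seg_proto <- stress_protocol(S_seg, t_on = t0, t_off = t1, horizon = t1)
      out <- deSolve::ode(
        y = y, times = seg_times,
        func = function(t, y, parms) {
          d <- beclin_rhs(y, t, parms, seg_proto, neg_tol = box_tol)
          list(unname(d), J = attr(d, "flux"))
        },
        parms = params, rtol = rtol, atol = atol, method = method
      )
    }
    if (attr(out, "istate")[1] < 0)
      stop("integrator failure in segment [", t0, ", ", t1, "]")
    rows[[i]] <- as.data.frame(unclass(out))
    y <- unlist(rows[[i]][nrow(rows[[i]]), c("B", "Bc", "A", "M", "C")])
  }
  traj <- do.call(rbind, rows)
  traj <- traj[!duplicated(traj$time), , drop = FALSE]
  traj <- traj[traj$time %in% times, , drop = FALSE]
  rownames(traj) <- NULL
  low <- min(traj$B, traj$Bc, traj$A, traj$M, traj$C)
  if (low < -box_tol || max(traj$C) > 1 + box_tol)
    stop("trajectory left the valid state box (min = ", format(low),
         ", max C = ", format(max(traj$C)), "): solver tolerance too loose")
  traj$B <- pmax(traj$B, 0); traj$Bc <- pmax(traj$Bc, 0)
  traj$A <- pmax(traj$A, 0); traj$M <- pmax(traj$M, 0)
  traj$C <- pmin(pmax(traj$C, 0), 1)
  traj$J <- autophagic_flux(traj$A, params)
  class(traj) <- c("beclin_trajectory", "data.frame")
  traj
}

#' Classify a trajectory as apoptotic
#'
#' A cell is apoptotic when its active Caspase-3 level strictly exceeds the
#' threshold (default 0.5) at the read-out time (default the end of the
#' trajectory).
#'
#' @param traj a `beclin_trajectory` from [simulate_cell()].
#' @param threshold Caspase-3 level defining apoptosis (strict `>`).
#' @param at read-out time (h); interpolated linearly if not on the grid.
#' @return logical.
#' @export
classify_apoptosis <- function(traj, threshold = 0.5, at = max(traj$time)) {
  if (at < min(traj$time) || at > max(traj$time))
    stop("read-out time outside the trajectory grid")
  C_at <- if (at %in% traj$time) traj$C[match(at, traj$time)]
          else approx(traj$time, traj$C, xout = at)$y
  C_at > threshold
}

# final Caspase level of a protocol run; fast path used by the experiments
final_caspase <- function(params, protocol, init, rtol = 1e-8, atol = 1e-10) {
  traj <- simulate_cell(params, protocol, init = init,
                        times = c(0, protocol$horizon),
                        rtol = rtol, atol = atol)
  traj$C[nrow(traj)]
}
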
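# Analysis of the isolated Caspase-3 switch.
#
# With the slow variables frozen, the Caspase equation reduces to
#   dC/dt = fact(C) - finact(C)
# with lumped drives alpha1 = alpha_C*M + sigma_C*A (activation) and
# alpha2 = sigma_J*J (IAP depletion). Saturation of both the activation and
# the inactivation term produces zero-order ultrasensitivity: the unforced
# system (alpha1 = alpha2 = 0) is bistable for suitable (mu_C, gamma_C,
# phi_C), and either drive destroys the survival state through a saddle-node
# bifurcation.

#' Parameters of the isolated Caspase-3 subsystem
#'
#' @param mu_C autocatalytic rate constant.
#' @param gamma_C degradation rate.
#' @param phi_C half-maximal Caspase level of both saturable terms.
#' @param alpha1 lumped activation drive `alpha_C*M + sigma_C*A`.
#' @param alpha2 lumped IAP-depletion drive `sigma_J*J`.
#' @return an object of class `switch_params`.
#' @export
switch_params <- function(mu_C = 1, gamma_C = 0.3, phi_C = 0.15,
                          alpha1 = 0, alpha2 = 0) {
  stopifnot(mu_C >= 0, gamma_C >= 0, phi_C > 0, alpha1 >= 0, alpha2 >= 0)
  structure(list(mu_C = mu_C, gamma_C = gamma_C, phi_C = phi_C,
                 alpha1 = alpha1, alpha2 = alpha2),
            class = "switch_params")
}

#' Caspase-3 activation and inactivation rates
#'
#' `caspase_activation` is
#' `(alpha1 + mu_C*C/(phi_C + 1 - C)) * (1 - C)`; `caspase_inactivation` is
#' `gamma_C*C / (phi_C + C + alpha2)`. Both vanish appropriately at the
#' boundaries: activation at C = 1, inactivation at C = 0.
#'
#' @param C active Caspase-3 level in \[0, 1\] (vectorised).
#' @param p a [switch_params()] object.
#' @return nonnegative rate(s).
#' @export
caspase_activation <- function(C, p) {
  if (any(C < 0 | C > 1)) stop("C must lie in [0, 1]")
  (p$alpha1 + p$mu_C * C / (p$phi_C + 1 - C)) * (1 - C)
}

#' @rdname caspase_activation
#' @export
caspase_inactivation <- function(C, p) {
  if (any(C < 0 | C > 1)) stop("C must lie in [0, 1]")
  p$gamma_C * C / (p$phi_C + C + p$alpha2)
}

# net Caspase rate; the quantity whose roots are the critical points
caspase_net_rate <- function(C, p) {
  caspase_activation(C, p) - caspase_inactivation(C, p)
}

#' Factorisation of the unforced Caspase balance
#'
#' For `alpha1 = alpha2 = 0` the net rate factorises as `g1(C) * g2(C)` with
#' `g1(C) = -mu_C*C / ((phi_C + 1 - C) * (phi_C + C))` (negative on (0, 1\])
#' and the quadratic
#' `g2(C) = C^2 + (phi_C - 1 - gamma_C/mu_C)*C +
#'  (-phi_C + gamma_C*phi_C/mu_C + gamma_C/mu_C)`,
#' so the nonzero critical points are the roots of `g2`.
#'
#' @param C Caspase level (vectorised).
#' @param p a [switch_params()] object (drives ignored).
#' @return numeric vector.
#' @export
caspase_g1 <- function(C, p) {
  -p$mu_C * C / ((p$phi_C + 1 - C) * (p$phi_C + C))
}

#' @rdname caspase_g1
#' @export
caspase_g2 <- function(C, p) {
  r <- p$gamma_C / p$mu_C
  C^2 + (p$phi_C - 1 - r) * C + (-p$phi_C + r * p$phi_C + r)
}

#' @rdname caspase_g1
#' @export
caspase_discriminant <- function(p) {
  r <- p$gamma_C / p$mu_C
  0.5 * ((p$phi_C - 1 - r)^2 - 4 * (-p$phi_C + r * p$phi_C + r))
}

#' Bistability condition of the unforced Caspase switch
#'
#' The unforced system (`alpha1 = alpha2 = 0`) is bistable iff the quadratic
#' factor `g2` has two roots in (0, 1\], which holds exactly when its
#' discriminant is positive and `g2(0) > 0`. The default parameters
#' (`mu_C = 1, gamma_C = 0.3, phi_C = 0.15`) give `g2(0) = 0.195` and
#' discriminant `0.27125`, hence bistability with critical points
#' 0 (stable), `gamma1` (unstable) and `gamma2` (stable).
#'
#' @param p a [switch_params()] object; its drives must be zero.
#' @return list with `bistable`, `delta` (the half-discriminant as used in
#'   the sign test), `g2_at_0`, and the roots `gamma1`, `gamma2` (NA when
#'   complex).
#' @export
caspase_cond1 <- function(p) {
  if (p$alpha1 != 0 || p$alpha2 != 0)
    stop("cond1 applies to the unforced system (alpha1 = alpha2 = 0)")
  delta <- caspase_discriminant(p)
  g2_0 <- caspase_g2(0, p)
  r <- p$gamma_C / p$mu_C
  b <- p$phi_C - 1 - r
  disc <- b^2 - 4 * g2_0
  roots <- if (disc >= 0) sort((-b + c(-1, 1) * sqrt(disc)) / 2) else c(NA, NA)
  list(bistable = delta > 0 && g2_0 > 0, delta = delta, g2_at_0 = g2_0,
       gamma1 = roots[1], gamma2 = roots[2])
}

#' Critical points of the Caspase balance
#'
#' Finds all roots of `fact(C) - finact(C)` in \[0, 1\] for arbitrary
#' nonnegative drives, by a dense sign scan (`n_sub` subintervals) refined
#' with bisection, and labels their stability by the sign of the derivative
#' of the net rate. For the unforced system the nonzero roots coincide with
#' the quadratic roots of `g2`.
#'
#' @param p a [switch_params()] object.
#' @param n_sub number of scan subintervals of \[0, 1\].
#' @param tol root tolerance.
#' @return data.frame with columns `C` (ascending) and `stability`
#'   ("stable"/"unstable"), with attribute `bistable` (TRUE iff the
#'   stable/unstable/stable three-point pattern is present).
#' @export
caspase_critical_points <- function(p, n_sub = 400, tol = 1e-10) {
  grid <- seq(0, 1, length.out = n_sub + 1)
  fv <- caspase_net_rate(grid, p)
  roots <- numeric(0)
  if (abs(fv[1]) < .Machine$double.eps * 10) roots <- 0
  for (i in seq_len(n_sub)) {
    if (fv[i] == 0 && i > 1) { roots <- c(roots, grid[i]); next }
    if (fv[i] * fv[i + 1] < 0) {
      rt <- uniroot(function(x) caspase_net_rate(x, p),
                    c(grid[i], grid[i + 1]), tol = min(tol, 1e-13))
      roots <- c(roots, rt$root)
    }
  }
  if (fv[n_sub + 1] == 0) roots <- c(roots, 1)
  roots <- sort(unique(roots))
  if (!length(roots))
    stop("no critical point found in [0, 1]; net rate has constant sign (",
         "f(0) = ", format(fv[1]), ", f(1) = ", format(fv[n_sub + 1]), ")")
  h <- 1e-6
  stab <- vapply(roots, function(r) {
    lo <- max(r - h, 0); hi <- min(r + h, 1)
    slope <- (caspase_net_rate(hi, p) - caspase_net_rate(lo, p)) / (hi - lo)
    if (slope < 0) "stable" else "unstable"
  }, character(1))
  out <- data.frame(C = roots, stability = stab)
  attr(out, "bistable") <- nrow(out) == 3 &&
    identical(stab, c("stable", "unstable", "stable"))
  out
}

#' One-parameter bifurcation scan over a Caspase drive
#'
#' Computes the critical-point set along a grid of drive values (`alpha1`,
#' the mitochondrial/autophagosome activation drive, or `alpha2`, the
#' IAP-depletion drive) and locates the saddle-node fold — the smallest
#' drive at which the low-Caspase survival branch disappears — by bisection
#' between the bracketing grid values.
#'
#' @param p a [switch_params()] object providing the fixed constants (its
#'   own drive values are overridden along the scan).
#' @param drive which drive to vary: `"alpha1"` or `"alpha2"`.
#' @param grid ascending nonnegative drive values.
#' @param fold_tol bisection tolerance for the fold location.
#' @return list with `branches` (data.frame `drive`, `C`, `stability`) and
#'   `fold` (drive value, NA if the survival branch never disappears on the
#'   grid).
#' @export
caspase_bifurcation <- function(p, drive = c("alpha1", "alpha2"), grid,
                                fold_tol = 1e-9) {
  drive <- match.arg(drive)
  if (is.unsorted(grid) || any(grid < 0))
    stop("grid must be ascending and nonnegative")
  at_drive <- function(a, n_sub = 400) {
    q <- p; q[[drive]] <- a
    caspase_critical_points(q, n_sub = n_sub)
  }
  # near the fold the merging roots close in on each other, so the
  # existence test needs a much denser scan than the branch tabulation;
  # with no activation drive the origin is a root whose stability is known
  # in closed form, which avoids boundary bias near the collision
  has_low <- function(a) {
    q <- p; q[[drive]] <- a
    if (q$alpha1 == 0 &&
        q$mu_C / (q$phi_C + 1) < q$gamma_C / (q$phi_C + q$alpha2))
      return(TRUE)
    cp <- at_drive(a, n_sub = 20000)
    any(cp$stability == "stable" & cp$C > 0 & cp$C < 0.5)
  }
  branches <- do.call(rbind, lapply(grid, function(a) {
    cp <- at_drive(a)
    data.frame(drive = a, C = cp$C, stability = cp$stability)
  }))
  low <- vapply(grid, has_low, logical(1))
  fold <- NA_real_
  if (any(low) && any(!low)) {
    i <- which(!low)[1]
    if (i == 1) stop("survival branch absent at the lowest grid value")
    lo <- grid[i - 1]; hi <- grid[i]
    while (hi - lo > fold_tol) {
      mid <- (lo + hi) / 2
      if (has_low(mid)) lo <- mid else hi <- mid
    }
    fold <- (lo + hi) / 2
  }
  list(branches = branches, fold = fold)
}

#' Survival-loss drive by the tangency/collision condition
#'
#' Independent computation of the drive value at which the survival state
#' disappears. Because the net rate is linear in either drive, the drive
#' can be solved from `fact - finact = 0` as a function `a(C)` along the
#' branch. Two mechanisms can remove the survival state: an interior
#' saddle-node, where root branches merge at a positive local maximum of
#' `a(C)`, or — for the IAP drive with no activation drive, where C = 0 is
#' a root at every drive value — a boundary collision, where the unstable
#' threshold root reaches C = 0 at the drive `a(0+)` and the origin loses
#' stability. The smallest positive candidate, i.e. the first loss met as
#' the drive grows from zero, is returned.
#'
#' @param p a [switch_params()] object (fixed constants; for the scanned
#'   drive the complementary drive is taken from `p`).
#' @param drive `"alpha1"` or `"alpha2"`.
#' @return fold drive value.
#' @export
caspase_fold_tangency <- function(p, drive = c("alpha1", "alpha2")) {
  drive <- match.arg(drive)
  a_of_C <- if (drive == "alpha1") {
    function(C) {
      p$gamma_C * C / ((p$phi_C + C + p$alpha2) * (1 - C)) -
        p$mu_C * C / (p$phi_C + 1 - C)
    }
  } else {
    function(C) {
      fa <- (p$alpha1 + p$mu_C * C / (p$phi_C + 1 - C)) * (1 - C)
      p$gamma_C * C / fa - p$phi_C - C
    }
  }
  grid <- seq(1e-6, 1 - 1e-4, length.out = 2001)
  av <- a_of_C(grid)
  cand <- numeric(0)
  for (i in 2:(length(grid) - 1)) {
    if (av[i] > av[i - 1] && av[i] > av[i + 1]) {
      opt <- stats::optimize(a_of_C, c(grid[i - 1], grid[i + 1]),
                             maximum = TRUE, tol = 1e-12)
      cand <- c(cand, opt$objective)
    }
  }
  # boundary collision of the threshold root with C = 0
  if (drive == "alpha2" && p$alpha1 == 0)
    cand <- c(cand, p$gamma_C * (p$phi_C + 1) / p$mu_C - p$phi_C)
  cand <- cand[cand > 0]
  if (!length(cand))
    stop("no survival-loss point: a(C) has no positive maximum or collision")
  min(cand)
}
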
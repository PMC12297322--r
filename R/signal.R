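#' Parameters of the explicit signalling model
#'
#' The Hill-type feedbacks can be expanded into explicit dynamics of two
#' effective signals: an activation signal `S_r` produced by lineage cells
#' (rate `R0 * c1`) and basally by non-lineage niche cells (rate `R1`),
#' degraded linearly and internalised by population `c2` (strength `betaR`);
#' and a self-renewal signal `S_b` produced basally, degraded linearly and
#' internalised by population `c3` (strength `betaB`). The cell-level rates
#' are `r = rbar * S_r` and `b = bbar * S_b`.
#'
#' @param R0 lineage production rate of the activation signal.
#' @param betaR,betaB internalisation strengths (> 0).
#' @param bbar conversion gain for self-renewal (equals `b0`), in (0, 1].
#' @param R1 basal production of the activation signal (0 in wild type).
#' @param rbar conversion gain for activation.
#' @return Object of class `"signal_params"`.
#' @seealso [qss_reduce()], [qss_expand()], [simulate_full_signal()]
#' @export
signal_parameters <- function(R0, betaR, betaB, bbar, R1 = 0, rbar = 1) {
  stopifnot("betaR and betaB must be positive" = betaR > 0 && betaB > 0,
            "R0, rbar must be positive; R1 nonnegative" =
              R0 > 0 && rbar > 0 && R1 >= 0,
            "bbar must lie in (0, 1]" = bbar > 0 && bbar <= 1)
  structure(list(R0 = R0, R1 = R1, betaR = betaR, betaB = betaB,
                 rbar = rbar, bbar = bbar),
            class = "signal_params")
}

#' Quasi-steady-state reduction of the signalling model
#'
#' Setting the fast signal equations to equilibrium recovers the Hill-type
#' feedback constants: `r0 = rbar R0 / betaR`, `r1 = rbar R1 / betaR`,
#' `K = 1 / betaR`, `b0 = bbar`, `beta = betaB`.
#'
#' @param sig a [signal_parameters()] object.
#' @return Named numeric vector `c(r0, r1, K, b0, beta)`.
#' @export
qss_reduce <- function(sig) {
  stopifnot(inherits(sig, "signal_params"))
  c(r0 = sig$rbar * sig$R0 / sig$betaR,
    r1 = sig$rbar * sig$R1 / sig$betaR,
    K = 1 / sig$betaR,
    b0 = sig$bbar,
    beta = sig$betaB)
}

#' Expand reduced feedback constants into signalling parameters
#'
#' Inverse of [qss_reduce()] up to a one-parameter gauge freedom: the
#' conversion gain `rbar` can be absorbed into the production rates, so the
#' expansion fixes the representative `rbar = 1` (any `rbar > 0` may be
#' supplied instead). `qss_reduce(qss_expand(p))` is the identity for any
#' choice of `rbar`.
#'
#' @param reduced named vector or list with `r0`, `K`, `b0`, `beta` and
#'   optionally `r1` (default 0), e.g. a [model_parameters()] object.
#' @param rbar the gauge representative to use for the conversion gain.
#' @return A [signal_parameters()] object.
#' @export
qss_expand <- function(reduced, rbar = 1) {
  r1 <- reduced[["r1"]] %||% 0
  betaR <- 1 / reduced[["K"]]
  signal_parameters(R0 = reduced[["r0"]] * betaR / rbar,
                    R1 = r1 * betaR / rbar,
                    betaR = betaR, betaB = reduced[["beta"]],
                    bbar = reduced[["b0"]], rbar = rbar)
}

#' Simulate the coupled cell-and-signal model
#'
#' Integrates the lineage system together with the explicit signal dynamics
#' \deqn{dS_r/dt = \kappa (R_1 + R_0 c_1 - S_r - \beta_r c_2 S_r),}
#' \deqn{dS_b/dt = \kappa (1 - S_b - \beta_b c_3 S_b),}
#' with `r = rbar S_r`, `b = bbar S_b` and kinetic speed-up factor
#' `speed` (\eqn{\kappa}). As `speed` grows the cell trajectory converges to
#' the reduced Hill model (quasi-steady-state limit); the default integrator
#' is implicit-capable because the fast-signal system is stiff.
#'
#' @param sig a [signal_parameters()] object.
#' @param params a [model_parameters()] object supplying the cell-side rates
#'   (`pA`, `pT`, `delta`, `n`); its feedback constants are ignored.
#' @param scenario a [scenario()] object choosing `c1`, `c2`, `c3`.
#' @param init initial [lineage_state()] (cell compartments only).
#' @param times increasing output times (days).
#' @param speed kinetic speed-up factor (>= 1).
#' @param signal_init optional initial `c(Sr, Sb)`; defaults to their
#'   quasi-steady values at `init`, which avoids an artificial transient.
#' @param rtol,atol integrator tolerances.
#' @return Trajectory data frame as in [simulate_lineage()] plus columns
#'   `Sr` and `Sb`.
#' @export
simulate_full_signal <- function(sig, params, scenario, init, times,
                                 speed = 1, signal_init = NULL,
                                 rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(sig, "signal_params"),
            "speed must be >= 1" = speed >= 1,
            "times must be increasing" = all(diff(times) > 0))
  init <- check_state(init, params)
  n <- params$n
  qss_signals <- function(state) {
    c1 <- .selector_value(state, scenario$c1)
    c2 <- .selector_value(state, scenario$c2)
    c3 <- .selector_value(state, scenario$c3)
    c(Sr = (sig$R1 + sig$R0 * c1) / (1 + sig$betaR * c2),
      Sb = 1 / (1 + sig$betaB * c3))
  }
  if (is.null(signal_init)) signal_init <- qss_signals(init)
  y0 <- c(init, Sr = unname(signal_init[1]), Sb = unname(signal_init[2]))

  fn <- function(t, y, parms) {
    cells <- pmax(y[seq_len(n + 4)], 0)
    names(cells) <- state_names(n)
    Sr <- max(y[["Sr"]], 0); Sb <- max(y[["Sb"]], 0)
    r <- sig$rbar * Sr
    b <- min(sig$bbar * Sb, 1)
    dcells <- .lineage_rhs_given_rb(cells, params, r, b)
    c1 <- .selector_value(cells, scenario$c1)
    c2 <- .selector_value(cells, scenario$c2)
    c3 <- .selector_value(cells, scenario$c3)
    dSr <- speed * (sig$R1 + sig$R0 * c1 - Sr - sig$betaR * c2 * Sr)
    dSb <- speed * (1 - Sb - sig$betaB * c3 * Sb)
    list(c(dcells, dSr, dSb))
  }
  out <- deSolve::ode(y = y0, times = times, func = fn, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("stiff integration failed; try a larger `rtol`/`atol` or an ",
         "implicit method via deSolve")
  df <- .traj_frame(out[, seq_len(n + 5), drop = FALSE], n)
  df$Sr <- out[, "Sr"]
  df$Sb <- out[, "Sb"]
  df
}

## Lineage derivatives for externally supplied (r, b) — shared by the
## explicit-signal model.
.lineage_rhs_given_rb <- function(state, params, r, b) {
  n <- params$n
  Q <- state[["Q"]]; A <- state[["A"]]
  Tv <- state[paste0("T", 0:n)]
  dQ <- -r * Q + 2 * b * params$pA * A
  dA <- r * Q - params$pA * A
  dT <- numeric(n + 1)
  dT[1] <- 2 * (1 - b) * params$pA * A - params$pT * Tv[1]
  for (i in seq_len(n))
    dT[i + 1] <- 2 * params$pT * Tv[i] - params$pT * Tv[i + 1]
  dN <- 2 * params$pT * Tv[n + 1] - params$delta * state[["N"]]
  stats::setNames(c(dQ, dA, dT, dN), state_names(n))
}
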
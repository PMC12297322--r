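## At any positive equilibrium the realized self-renewal fraction must be
## exactly 1/2 (d(Q+A)/dt = (2b - 1) pA A = 0 with A > 0), which pins the
## inhibitor population at c3bar = (2 b0 - 1) / beta. The downstream cascade
## then gives T0 = pA A / pT, Ti = 2 T(i-1), N = 2^(n+1) pA A / delta.
## This block builds the damped-Newton initial guess from that structure.
.equilibrium_guess <- function(params, scenario) {
  b0 <- params$b0; beta <- params$beta
  c3bar <- (2 * b0 - 1) / beta
  if (c3bar <= 0) return(NULL)
  n <- params$n
  pA <- params$pA; pT <- params$pT; delta <- params$delta
  A <- switch(scenario$c3,
              "A" = c3bar,
              "Q" = NA_real_,
              "Q+A" = c3bar / 3,
              "T0" = pT * c3bar / pA,
              "sumT" = pT * c3bar / (pA * (2^(n + 1) - 1)),
              "N" = delta * c3bar / (2^(n + 1) * pA))
  r1 <- if (scenario$uses_r1) params$r1 else 0
  if (scenario$c3 == "Q") {
    # Q pinned; A from the activation balance r(Q,.) Q = pA A
    Q <- c3bar
    c2g <- switch(scenario$c2, "A" = 0, "Q+A" = Q, "T0" = 0, Q)
    A <- (r1 + params$r0 * Q) * Q / (params$pA * (params$K + c2g))
  } else if (scenario$c1 == "Q+A") {
    S <- c3bar  # c3 = Q+A in the registry whenever c1 = Q+A
    r <- (r1 + params$r0 * S) / (params$K + S)
    A <- r * S / (r + pA)
    Q <- S - A
  } else {
    # c1 = Q: r0 Q^2 ~ pA A (K + c2), ignore r1 for the guess
    c2g <- switch(scenario$c2, "A" = A, "Q+A" = A, "T0" = pA * A / pT, 0)
    Q <- sqrt(pA * A * (params$K + c2g) / params$r0)
  }
  if (!is.finite(A) || !is.finite(Q) || A <= 0 || Q <= 0) return(NULL)
  T0 <- pA * A / pT
  lineage_state(Q = Q, A = A, T = T0 * 2^(0:n),
                N = 2^(n + 1) * pA * A / delta)
}

## Damped Newton iteration on the full right-hand side.
.newton_equilibrium <- function(params, scenario, x0, max_iter = 100,
                                tol = 1e-11) {
  rhs <- .make_rhs(params, scenario, neg_tol = Inf)
  nms <- state_names(params$n)
  f <- function(x) stats::setNames(rhs(pmax(unname(x), 0)), nms)
  x <- x0
  scale <- function(x) max(1, max(abs(x)))
  for (it in seq_len(max_iter)) {
    fx <- f(x)
    if (max(abs(fx)) / scale(x) < tol) break
    J <- num_jacobian(f, x, h = pmax(1e-7 * abs(x), 1e-10))
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(step)) step <- -drop(MASS::ginv(J) %*% fx)
    lambda <- 1
    f0 <- sum(fx^2)
    repeat {
      xn <- x + lambda * step
      fn <- tryCatch(sum(f(xn)^2), error = function(e) Inf)
      if (fn < f0 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    x <- xn
  }
  fx <- f(x)
  list(state = x, residual = max(abs(fx)) / scale(x),
       converged = max(abs(fx)) / scale(x) < 1e-8)
}

.steady_state_result <- function(state, kind, params, scenario) {
  rhs <- .make_rhs(params, scenario, neg_tol = Inf)
  nms <- state_names(params$n)
  f <- function(x) stats::setNames(rhs(unname(x)), nms)
  J <- num_jacobian(f, state, h = pmax(1e-6 * abs(state), 1e-8))
  ev <- eigen(J, only.values = TRUE)$values
  structure(list(state = state, kind = kind, eigenvalues = ev,
                 stable = max(Re(ev)) < 0,
                 residual = max(abs(f(state))) / max(1, max(abs(state)))),
            class = "steady_state_result")
}

#' Steady states of the lineage model
#'
#' Finds the equilibria of the system for a given scenario. The trivial
#' (extinction) equilibrium always exists. A positive equilibrium exists
#' exactly when the maximal self-renewal fraction exceeds one half
#' (`b0 > 1/2`); at it the realized self-renewal fraction equals 1/2.
#' The positive equilibrium is located by a damped Newton iteration started
#' from the semi-closed-form guess implied by that condition; for the
#' scenario `r(Q,A),b(A)` the result agrees with the closed form
#' \eqn{\bar A = (2 b_0 - 1)/\beta},
#' \eqn{\bar Q = \sqrt{(p_A/r_0) \bar A (K + \bar A)}}.
#'
#' @inheritParams feedback_rates
#' @return A list of `"steady_state_result"` objects (fields `state`, `kind`
#'   = `"trivial"` or `"positive"`, `eigenvalues`, `stable`, `residual`).
#'   Length 1 when `b0 <= 1/2`, length 2 otherwise.
#' @examples
#' p <- model_parameters(r0 = 1, K = 100, b0 = 0.75, beta = 0.01, pA = 1)
#' ss <- steady_states(p, scenario("r(Q,A),b(A)"))
#' ss[[2]]$state[c("Q", "A")]  # Abar = 50, Qbar = sqrt(50 * 150)
#' @export
steady_states <- function(params, scenario) {
  zero <- lineage_state(0, 0, rep(0, params$n + 1), 0)
  out <- list(.steady_state_result(zero, "trivial", params, scenario))
  guess <- .equilibrium_guess(params, scenario)
  if (!is.null(guess)) {
    sol <- .newton_equilibrium(params, scenario, guess)
    if (sol$converged && all(sol$state > 0)) {
      out <- c(out, list(.steady_state_result(sol$state, "positive",
                                              params, scenario)))
    } else if (!sol$converged) {
      warning(sprintf(
        "positive-equilibrium search did not converge (residual %.3g)",
        sol$residual))
    }
  }
  out
}

#' Linear stability of an equilibrium
#'
#' Numerical Jacobian of the right-hand side at the supplied equilibrium and
#' its eigenvalues; the equilibrium is classified stable when every
#' eigenvalue has negative real part. For `b0 > 1/2` the trivial equilibrium
#' is not stable (the NSC pool can grow away from extinction).
#'
#' @inheritParams feedback_rates
#' @param equilibrium a state vector with small right-hand-side residual.
#' @return A `"steady_state_result"` object.
#' @export
stability <- function(params, scenario, equilibrium) {
  equilibrium <- check_state(equilibrium, params)
  kind <- if (all(equilibrium == 0)) "trivial" else "positive"
  res <- .steady_state_result(equilibrium, kind, params, scenario)
  if (res$residual > 1e-6)
    warning(sprintf("supplied state has residual %.3g; not an equilibrium?",
                    res$residual))
  res
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf("%s steady state (%s), residual %.2e\n",
              x$kind, if (x$stable) "stable" else "not stable", x$residual))
  print(round(x$state, 4))
  cat("eigenvalue real parts:",
      paste(sprintf("%.4g", Re(x$eigenvalues)), collapse = ", "), "\n")
  invisible(x)
}

#' Maximum NSC-pool growth rate over a grid of nonnegative states
#'
#' Evaluates \eqn{dQ/dt + dA/dt} from the model right-hand side on the full
#' grid of nonnegative `(Q, A, v)` states, where `v` fills every downstream
#' compartment so that the self-renewal inhibitor takes a grid value
#' whichever population it is, and returns the maximum over the grid and
#' the given scenarios. With `b0 = 1/2` this maximum is the sharp depletion
#' bound: the total NSC pool can never grow.
#'
#' @param params a [model_parameters()] object.
#' @param grid nonnegative grid values used for each of Q, A and the
#'   inhibitor fill value.
#' @param scenarios character vector of registry names.
#' @return The maximum of \eqn{d(Q+A)/dt} (cells/day) over the grid.
#' @export
depletion_grid_max <- function(params,
                               grid = seq(0, 5000, length.out = 50),
                               scenarios = list_scenarios(TRUE)) {
  stopifnot(all(grid >= 0))
  g <- expand.grid(Q = grid, A = grid, v = grid)
  n <- params$n
  val <- function(sel) switch(sel,
                              "Q" = g$Q, "A" = g$A, "Q+A" = g$Q + g$A,
                              "T0" = g$v, "sumT" = (n + 1) * g$v,
                              "N" = g$v)
  worst <- -Inf
  for (nm in scenarios) {
    sc <- scenario(nm)
    r1 <- if (sc$uses_r1) params$r1 else 0
    r <- (r1 + params$r0 * val(sc$c1)) / (params$K + val(sc$c2))
    b <- params$b0 / (1 + params$beta * val(sc$c3))
    dQ <- -r * g$Q + 2 * b * params$pA * g$A
    dA <- r * g$Q - params$pA * g$A
    worst <- max(worst, max(dQ + dA))
  }
  worst
}

#' Numerically locate the self-renewal bifurcation threshold
#'
#' Bisects on `b0` for the existence of a positive equilibrium (all other
#' parameters held fixed). The positive branch emerges from the origin at
#' `b0 = 1/2` in every scenario, since the equilibrium condition pins the
#' inhibitor population at `(2 b0 - 1) / beta`.
#'
#' @inheritParams feedback_rates
#' @param interval search interval for `b0`.
#' @param tol bisection tolerance on `b0`.
#' @return List with the bracketing values `lower` (no positive equilibrium)
#'   and `upper` (positive equilibrium exists) and their midpoint
#'   `threshold`.
#' @export
bifurcation_threshold <- function(params, scenario,
                                  interval = c(0.3, 0.95), tol = 1e-6) {
  has_positive <- function(b0) {
    p <- update_params(params, list(b0 = b0))
    length(suppressWarnings(steady_states(p, scenario))) > 1
  }
  lo <- interval[1]; hi <- interval[2]
  if (has_positive(lo) || !has_positive(hi))
    stop("interval does not bracket the bifurcation")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (has_positive(mid)) hi <- mid else lo <- mid
  }
  list(lower = lo, upper = hi, threshold = (lo + hi) / 2)
}
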
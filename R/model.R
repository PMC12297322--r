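#' Evaluate the feedback-regulated activation and self-renewal rates
#'
#' Computes the activation rate \eqn{r = (r_1 + r_0 c_1)/(K + c_2)} (with
#' \eqn{r_1 = 0} unless the scenario uses the extended numerator) and the
#' self-renewal fraction \eqn{b = b_0/(1 + \beta c_3)} at a given state.
#'
#' @param state a [lineage_state()] vector.
#' @param params a [model_parameters()] object.
#' @param scenario a [scenario()] object.
#' @return Named numeric vector `c(r, b)`; `r >= 0` (1/day) and
#'   `b` in `(0, b0]`.
#' @examples
#' p <- model_parameters(r0 = 1, K = 1, b0 = 0.5, beta = 0)
#' # beta = 0 not allowed; use a tiny beta for a pure-r example instead:
#' p <- model_parameters(r0 = 1, K = 1, b0 = 0.5, beta = 1e-9)
#' s <- lineage_state(Q = 1, A = 1)
#' feedback_rates(s, p, scenario("r(Q,A),b(A)"))  # r = 0.5
#' @export
feedback_rates <- function(state, params, scenario) {
  state <- check_state(state, params)
  c1 <- .selector_value(state, scenario$c1)
  c2 <- .selector_value(state, scenario$c2)
  c3 <- .selector_value(state, scenario$c3)
  r1 <- if (scenario$uses_r1) params$r1 else 0
  c(r = (r1 + params$r0 * c1) / (params$K + c2),
    b = params$b0 / (1 + params$beta * c3))
}

## Build a fast derivative closure over positional indices: the integrator
## calls the right-hand side thousands of times, so selector resolution,
## name handling and parameter lookup happen once here, not per call.
## `d_kill` adds the chemotherapy death rate to A and all TAP compartments
## (0 outside a treatment window). Small negative state values (integrator
## probing) are clipped to zero before evaluating rates; negatives beyond
## `neg_tol` indicate misuse and raise an error.
.make_rhs <- function(params, scenario, d_kill = 0, neg_tol = 1e-6) {
  n <- params$n
  iT <- 3:(n + 3)
  iN <- n + 4L
  pick <- function(sel) {
    force(sel)
    switch(sel,
           "Q" = function(x) x[1],
           "A" = function(x) x[2],
           "Q+A" = function(x) x[1] + x[2],
           "T0" = function(x) x[3],
           "sumT" = function(x) sum(x[iT]),
           "N" = function(x) x[iN],
           stop(sprintf("unknown population selector '%s'; valid: %s",
                        sel, paste(.selectors, collapse = ", "))))
  }
  f1 <- pick(scenario$c1); f2 <- pick(scenario$c2); f3 <- pick(scenario$c3)
  r1 <- if (scenario$uses_r1) params$r1 else 0
  r0 <- params$r0; K <- params$K; b0 <- params$b0; beta <- params$beta
  pA <- params$pA; pT <- params$pT; delta <- params$delta
  function(x) {
    if (any(x < -neg_tol))
      stop(sprintf(
        "state has negative component(s) beyond tolerance: min = %g",
        min(x)))
    x <- pmax(x, 0)
    r <- (r1 + r0 * f1(x)) / (K + f2(x))
    b <- b0 / (1 + beta * f3(x))
    Tv <- x[iT]
    kill <- d_kill
    c(-r * x[1] + 2 * b * pA * x[2],
      r * x[1] - pA * x[2] - kill * x[2],
      2 * (1 - b) * pA * x[2] - (pT + kill) * Tv[1],
      2 * pT * Tv[-(n + 1)] - (pT + kill) * Tv[-1],
      2 * pT * Tv[n + 1] - delta * x[iN])
  }
}

.rhs_core <- function(state, params, scenario, d_kill = 0, neg_tol = 1e-6) {
  f <- .make_rhs(params, scenario, d_kill, neg_tol)
  stats::setNames(f(unname(state)), state_names(params$n))
}

## Parameter vector for the compiled derivative routine (src/lineage.c).
.sel_code <- c("Q" = 1, "A" = 2, "Q+A" = 3, "T0" = 4, "sumT" = 5, "N" = 6)

.c_parms <- function(params, scenario, d_kill = 0) {
  c(params$r0, if (scenario$uses_r1) params$r1 else 0, params$K,
    params$b0, params$beta, params$pA, params$pT, params$delta,
    .sel_code[[scenario$c1]], .sel_code[[scenario$c2]],
    .sel_code[[scenario$c3]], d_kill)
}

## Integrate with the compiled RHS and check the nonnegativity contract.
.integrate <- function(init, times, params, scenario, d_kill, method,
                       rtol, atol) {
  if (length(times) == 1) {
    out <- cbind(time = times, matrix(init, nrow = 1,
                                      dimnames = list(NULL, names(init))))
    return(out)
  }
  out <- deSolve::ode(y = init, times = times, func = "lineage_derivs",
                      parms = .c_parms(params, scenario, d_kill),
                      dllname = "nscfeedback",
                      initfunc = "lineage_initmod",
                      method = method, rtol = rtol, atol = atol)
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1] < 0)
    stop("ODE integration failed (step-size collapse?); diagnostics:\n",
         paste(utils::capture.output(
           deSolve::diagnostics.deSolve(out)), collapse = "\n"))
  out
}

#' Right-hand side of the lineage ODE system
#'
#' Time derivative of the state under the healthy (unperturbed) model:
#' \deqn{dQ/dt = -rQ + 2 b p_A A, \quad dA/dt = rQ - p_A A,}
#' \deqn{dT_0/dt = 2(1-b) p_A A - p_T T_0, \quad
#'       dT_i/dt = 2 p_T T_{i-1} - p_T T_i,}
#' \deqn{dN/dt = 2 p_T T_n - \delta N,}
#' with `r` and `b` from [feedback_rates()]. The identity
#' \eqn{d(Q+A)/dt = (2b - 1) p_A A} holds exactly, which is the source of
#' the bifurcation at \eqn{b_0 = 1/2}.
#'
#' @inheritParams feedback_rates
#' @param t time (days); the autonomous system ignores it.
#' @return Named derivative vector, same layout as the state.
#' @export
rhs_lineage <- function(t, state, params, scenario) {
  state <- check_state(state, params)
  .rhs_core(state, params, scenario, d_kill = 0)
}

#' Right-hand side of the lineage system under chemotherapy
#'
#' As [rhs_lineage()] but with an additional death rate `d` applied to the
#' actively dividing compartments (`A` and every TAP compartment), modelling
#' killing by temozolomide during the treatment window. `d = 0` reduces
#' exactly to the unperturbed system.
#'
#' @inheritParams rhs_lineage
#' @param d chemotherapy death rate (1/day), nonnegative.
#' @export
rhs_tmz <- function(t, state, params, scenario, d) {
  stopifnot("death rate d must be nonnegative" = d >= 0)
  state <- check_state(state, params)
  .rhs_core(state, params, scenario, d_kill = d)
}

.traj_frame <- function(out, n) {
  df <- as.data.frame(out)
  names(df)[1] <- "time_days"
  obs <- t(apply(as.matrix(df[, state_names(n)]), 1, state_observables))
  cbind(df, as.data.frame(obs))
}

#' Simulate the lineage model
#'
#' Integrates the system with a stiff-capable solver and returns the
#' trajectory together with the derived observables (total NSCs, fraction
#' active, total TAPs, neuroblasts).
#'
#' @inheritParams feedback_rates
#' @param init initial [lineage_state()].
#' @param times increasing vector of output times (days).
#' @param rtol,atol relative and absolute integrator tolerances.
#' @param method `deSolve` integration method.
#' @return A data frame with columns `time_days`, `Q`, `A`, `T0..Tn`, `N`,
#'   `nsc_total`, `frac_active`, `tap_total`, `nb_total`.
#' @examples
#' p <- default_parameters()
#' tr <- simulate_lineage(p, scenario("r(Q,A),b(Q)"),
#'                        initial_state(p, tap_total = 2000, nb_total = 9000),
#'                        times = seq(30, 700, by = 10))
#' head(tr[, c("time_days", "nsc_total", "frac_active")])
#' @export
simulate_lineage <- function(params, scenario, init, times,
                             rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot("times must be increasing" = all(diff(times) > 0),
            "init must be nonnegative" = all(init >= 0))
  init <- check_state(init, params)
  out <- .integrate(init, times, params, scenario, 0, method, rtol, atol)
  .traj_frame(out, params$n)
}

#' Export a trajectory to CSV
#'
#' @param traj a trajectory from [simulate_lineage()] or [simulate_tmz()].
#' @param path output file path.
#' @export
export_trajectory <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chemotherapy (TMZ) treatment protocol
#'
#' Describes one temozolomide experiment: the drug is administered at
#' `treatment_age` and kills dividing cells at rate `d` for `window` days;
#' afterwards the healthy system resumes, possibly with altered parameters
#' (`post_params`), reflecting selection of slow-cycling cells by the drug.
#' Section-level BrdU+ counts relate to whole-region counts through the
#' scaling factor `rho` (whole region = `rho` x section).
#'
#' @param treatment_age age at drug administration (days).
#' @param d chemotherapy death rate of A and TAP compartments (1/day).
#' @param rho section-to-whole-region scaling factor (> 0).
#' @param window duration of the killing regime (days).
#' @param post_params [model_parameters()] used after the window; defaults to
#'   the pre-treatment parameters.
#' @return Object of class `"tmz_protocol"`.
#' @export
tmz_protocol <- function(treatment_age, d, rho, window = 3,
                         post_params = NULL) {
  stopifnot("d must be nonnegative" = d >= 0,
            "rho must be positive" = rho > 0,
            "window must be positive" = window > 0,
            "treatment_age must be positive" = treatment_age > 0)
  structure(list(treatment_age = treatment_age, window = window,
                 d = d, rho = rho, post_params = post_params),
            class = "tmz_protocol")
}

#' Simulate a TMZ perturbation experiment
#'
#' Three-regime piecewise integration: the healthy system with the
#' pre-treatment parameters up to `treatment_age`, the killing system
#' ([rhs_tmz()]) during the treatment window, and the healthy system with
#' the protocol's `post_params` afterwards. The state is continuous at both
#' switch times. The proliferating (BrdU+) pool `A + sum(Ti)` is reported at
#' whole-region scale (`brdu_total`) and at section scale
#' (`brdu_section = brdu_total / rho`).
#'
#' @param protocol a [tmz_protocol()].
#' @inheritParams simulate_lineage
#' @return Trajectory data frame as in [simulate_lineage()] plus columns
#'   `brdu_total` and `brdu_section`.
#' @export
simulate_tmz <- function(protocol, params, scenario, init, times,
                         rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(protocol, "tmz_protocol"),
            "times must be increasing" = all(diff(times) > 0))
  t_on <- protocol$treatment_age
  t_off <- t_on + protocol$window
  if (t_on < times[1] || t_on > times[length(times)])
    stop("treatment_age must lie inside the span of `times`")
  post_params <- protocol$post_params %||% params
  init <- check_state(init, params)

  run <- function(y0, tt, prm, d_kill) {
    if (length(tt) < 2) return(NULL)
    .integrate(y0, tt, prm, scenario, d_kill, method, rtol, atol)
  }
  segment_times <- function(lo, hi) {
    inner <- times[times > lo & times < hi]
    unique(c(lo, inner, hi))
  }

  t_end <- times[length(times)]
  pieces <- list()
  y <- init
  # pre-treatment regime
  tt <- segment_times(times[1], min(t_on, t_end))
  out <- run(y, tt, params, 0)
  if (!is.null(out)) { pieces$pre <- out; y <- out[nrow(out), -1] }
  # killing regime
  if (t_end > t_on) {
    tt <- segment_times(t_on, min(t_off, t_end))
    out <- run(y, tt, params, protocol$d)
    if (!is.null(out)) { pieces$during <- out; y <- out[nrow(out), -1] }
  }
  # recovery regime
  if (t_end > t_off) {
    tt <- segment_times(t_off, t_end)
    out <- run(y, tt, post_params, 0)
    if (!is.null(out)) pieces$post <- out
  }

  all_out <- do.call(rbind, pieces)
  # keep requested output times plus the two switch times
  keep <- !duplicated(all_out[, 1])
  all_out <- all_out[keep, , drop = FALSE]
  df <- .traj_frame(all_out, params$n)
  df$brdu_total <- df$A + df$tap_total
  df$brdu_section <- df$brdu_total / protocol$rho
  rownames(df) <- NULL
  df
}
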
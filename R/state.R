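state_names <- function(n) c("Q", "A", paste0("T", 0:n), "N")

#' Construct a lineage state vector
#'
#' A state holds whole-region cell counts for the quiescent NSCs (`Q`),
#' active NSCs (`A`), the `n + 1` TAP compartments (`T0..Tn`) and
#' neuroblasts (`N`).
#'
#' @param Q,A,N scalar counts (cells).
#' @param T numeric vector of TAP compartment counts, length `n + 1`.
#' @return Named numeric vector `c(Q, A, T0..Tn, N)`.
#' @examples
#' lineage_state(Q = 1300, A = 600, T = rep(200, 4), N = 5000)
#' @export
lineage_state <- function(Q, A, T = rep(0, 4), N = 0) {
  stopifnot(
    "all state components must be nonnegative" =
      all(c(Q, A, T, N) >= 0),
    "need at least 2 TAP compartments (n >= 1)" = length(T) >= 2
  )
  n <- length(T) - 1L
  stats::setNames(c(Q, A, T, N), state_names(n))
}

## Assert that a state vector matches the parameter set's compartment count.
check_state <- function(state, params) {
  want <- state_names(params$n)
  if (length(state) != length(want))
    stop(sprintf("state has length %d but n = %d requires length %d",
                 length(state), params$n, length(want)))
  if (is.null(names(state)) || !all(names(state) == want))
    names(state) <- want
  state
}

#' Observables derived from a state
#'
#' Maps a state to the four quantities measured in mice: total NSC count
#' `Q + A`, fraction of active NSCs `A / (Q + A)`, total TAP count
#' \eqn{\sum_i T_i} and neuroblast count `N`.
#'
#' @param state a [lineage_state()] vector.
#' @return Named numeric vector `nsc_total`, `frac_active`, `tap_total`,
#'   `nb_total`.
#' @export
state_observables <- function(state) {
  n <- length(state) - 4L
  Q <- state[["Q"]]; A <- state[["A"]]
  tap <- sum(state[paste0("T", 0:n)])
  c(nsc_total = Q + A,
    frac_active = if (Q + A > 0) A / (Q + A) else 0,
    tap_total = tap,
    nb_total = state[["N"]])
}

#' Build an initial state from the fixed total NSC count
#'
#' Splits `NSC0` between quiescent and active cells by the initial active
#' fraction `f0`, distributes an initial TAP total equally across the
#' `n + 1` TAP compartments (data only constrain the total), and sets the
#' neuroblast count.
#'
#' @param params a [model_parameters()] object (supplies `NSC0` and `n`).
#' @param f0 initial fraction of active NSCs.
#' @param tap_total,nb_total initial TAP and neuroblast totals (cells).
#' @return A [lineage_state()] vector.
#' @export
initial_state <- function(params, f0 = 0.3, tap_total = 0, nb_total = 0) {
  stopifnot(f0 >= 0, f0 <= 1, tap_total >= 0, nb_total >= 0)
  lineage_state(Q = (1 - f0) * params$NSC0, A = f0 * params$NSC0,
                T = rep(tap_total / (params$n + 1), params$n + 1),
                N = nb_total)
}
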
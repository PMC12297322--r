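#' Model parameters for the neural lineage system
#'
#' Bundles the kinetic constants of the lineage model. The activation rate of
#' quiescent NSCs is \eqn{r = (r_1 + r_0 c_1)/(K + c_2)} and the self-renewal
#' fraction of active NSCs is \eqn{b = b_0/(1 + \beta c_3)}, where the
#' \eqn{c_i} are lineage subpopulation sizes chosen by a
#' [scenario()]. Proliferation and exit rates are fixed at their
#' experimentally derived values by default and are normally not fitted.
#'
#' @param r0 activation amplitude (1/day).
#' @param K activation half-saturation constant (cells).
#' @param b0 maximal self-renewal fraction, in (0, 1].
#' @param beta self-renewal inhibition strength (1/cells).
#' @param r1 basal activation production (cells/day); 0 in wild type, positive
#'   in the interferon-receptor knockout where non-lineage cells drive
#'   activation.
#' @param pA division rate of active NSCs (1/day).
#' @param pT division rate of transient amplifying progenitors (1/day).
#' @param delta neuroblast exit rate (1/day).
#' @param n number of TAP amplification steps (integer, \eqn{\ge 1}), giving
#'   `n + 1` TAP compartments.
#' @param NSC0 total NSC count (Q + A) at the start of a simulation (cells).
#'
#' @return An object of class `"lineage_params"`: a named list of the above.
#' @examples
#' p <- model_parameters(r0 = 0.05, K = 1000, b0 = 0.9, beta = 0.0027)
#' p$pA
#' @export
model_parameters <- function(r0, K, b0, beta, r1 = 0,
                             pA = 0.95, pT = 0.81, delta = 0.19,
                             n = 3L, NSC0 = 1900) {
  n <- as.integer(n)
  p <- list(r0 = r0, r1 = r1, K = K, b0 = b0, beta = beta,
            pA = pA, pT = pT, delta = delta, n = n, NSC0 = NSC0)
  stopifnot(
    "r0, K, beta, pA, pT, delta, NSC0 must be strictly positive" =
      all(unlist(p[c("r0", "K", "beta", "pA", "pT", "delta", "NSC0")]) > 0),
    "r1 must be nonnegative" = r1 >= 0,
    "b0 must lie in (0, 1]" = b0 > 0 && b0 <= 1,
    "n must be >= 1" = n >= 1L
  )
  structure(p, class = "lineage_params")
}

#' Default parameter set used throughout the package
#'
#' The canonical wild-type-like parameter set: fixed rates at their
#' experimentally derived values (`pA = 0.95`, `pT = 0.81`, `delta = 0.19`,
#' `NSC0 = 1900`, `n = 3`) and feedback constants chosen so that the lineage
#' declines from roughly 1900 NSCs over 30--700 days of age towards a positive
#' steady state, with an initial active fraction near 0.3 — the regime the
#' observed mouse data occupy.
#'
#' @return A [model_parameters()] object.
#' @export
default_parameters <- function() {
  model_parameters(r0 = 0.2, K = 1000, b0 = 0.52, beta = 7.3e-5)
}

#' @export
print.lineage_params <- function(x, ...) {
  cat("Lineage model parameters\n")
  cat(sprintf("  activation:   r0 = %g /day, r1 = %g cells/day, K = %g cells\n",
              x$r0, x$r1, x$K))
  cat(sprintf("  self-renewal: b0 = %g, beta = %g /cells\n", x$b0, x$beta))
  cat(sprintf("  fixed rates:  pA = %g, pT = %g, delta = %g /day\n",
              x$pA, x$pT, x$delta))
  cat(sprintf("  structure:    n = %d amplification steps, NSC0 = %g cells\n",
              x$n, x$NSC0))
  invisible(x)
}

## Replace a named subset of parameters (used by the fitting machinery).
update_params <- function(params, values) {
  for (nm in names(values)) params[[nm]] <- unname(values[[nm]])
  model_parameters(r0 = params$r0, K = params$K, b0 = params$b0,
                   beta = params$beta, r1 = params$r1, pA = params$pA,
                   pT = params$pT, delta = params$delta, n = params$n,
                   NSC0 = params$NSC0)
}
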
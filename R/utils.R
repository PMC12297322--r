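#' @keywords internal
#' @useDynLib nscfeedback
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Truncated-normal draws via inverse CDF; vectorised over mean/sd.
## Used for per-mouse observation noise and randomized initial conditions.
rtnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (any(sd < 0)) stop("sd must be nonnegative")
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    plo <- stats::pnorm(lower, mean[pos], sd[pos])
    phi <- stats::pnorm(upper, mean[pos], sd[pos])
    if (any(phi - plo < 1e-12)) stop("truncation interval has negligible mass")
    u <- stats::runif(sum(pos), plo, phi)
    out[pos] <- stats::qnorm(u, mean[pos], sd[pos])
  }
  pmin(pmax(out, lower), upper)
}

## Seed an expression's RNG without clobbering the caller's stream (a
## likelihood evaluated inside a sampler must not reset the sampler's
## proposals).
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  do.call(on.exit, list(quote(nscfeedback:::restore_rng(.rng_backup)),
                        add = TRUE), envir = envir)
  assign(".rng_backup", old, envir = envir)
  set.seed(seed)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

## Central-difference Jacobian of a vector-valued function.
num_jacobian <- function(f, x, h = NULL) {
  fx <- f(x)
  m <- length(fx)
  d <- length(x)
  if (is.null(h)) h <- pmax(1e-7 * abs(x), 1e-8)
  J <- matrix(0, m, d)
  for (j in seq_len(d)) {
    xp <- xm <- x
    xp[j] <- x[j] + h[j]
    xm[j] <- x[j] - h[j]
    J[, j] <- (f(xp) - f(xm)) / (2 * h[j])
  }
  dimnames(J) <- list(names(fx), names(x))
  J
}
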
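#' Exponential variance-decay model for cross-mouse scatter
#'
#' Trajectories started from varying initial conditions contract quickly,
#' so the cross-mouse standard deviation of an observable is modelled as
#' \eqn{\sigma(t) = d_0 + d_1 e^{-d_3 t}} with `t` measured from the first
#' observation age. `fit_variance_decay()` least-squares fits this curve to
#' the per-age sample SDs of one observable; the result interpolates
#' \eqn{\sigma} at sparsely sampled ages and provides the SD of the
#' initial-condition distribution at the time origin.
#'
#' @param dataset a longitudinal dataset (one setting).
#' @param observable which observable to model.
#' @return Object of class `"variance_model"` with fields `d0`, `d1`, `d3`
#'   (1/day), `t0` (the age anchoring `t = 0`) and `observable`.
#' @export
fit_variance_decay <- function(dataset, observable) {
  validate_dataset(dataset)
  sub <- dataset[dataset$observable == observable, , drop = FALSE]
  if (!nrow(sub)) stop("no records for observable ", observable)
  g <- dataset_groups(sub)
  g <- g[g$n_mice >= 2 & !is.na(g$var) & g$var > 0, , drop = FALSE]
  t0 <- min(sub$age_days)
  if (nrow(g) < 3) {
    pooled <- stats::sd(sub$value)
    if (is.na(pooled) || pooled <= 0)
      stop("insufficient replication to estimate any scatter for ",
           observable)
    warning("fewer than 3 replicated ages for ", observable,
            "; falling back to pooled SD (constant sigma)")
    return(structure(list(d0 = pooled, d1 = 0, d3 = 0, t0 = t0,
                          observable = observable),
                     class = "variance_model"))
  }
  tt <- g$age_days - t0
  sds <- sqrt(g$var)
  obj <- function(par) {
    d0 <- exp(par[1]); d1 <- exp(par[2]); d3 <- exp(par[3])
    sum((d0 + d1 * exp(-d3 * tt) - sds)^2)
  }
  span <- max(tt) - min(tt)
  init <- c(log(max(min(sds), 1e-8)),
            log(max(max(sds) - min(sds), 1e-8)),
            log(3 / max(span, 1)))
  opt <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  structure(list(d0 = exp(opt$par[1]), d1 = exp(opt$par[2]),
                 d3 = exp(opt$par[3]), t0 = t0, observable = observable),
            class = "variance_model")
}

#' @rdname fit_variance_decay
#' @param vm a `"variance_model"`.
#' @param age_days ages (days) at which to evaluate \eqn{\sigma}.
#' @export
predict_sd <- function(vm, age_days) {
  stopifnot(inherits(vm, "variance_model"))
  vm$d0 + vm$d1 * exp(-vm$d3 * (age_days - vm$t0))
}

#' Sample an initial state from observable-level Gaussians
#'
#' Draws the four measured quantities (total NSCs `S`, active fraction `f`,
#' TAP total, NB total) from truncated Gaussians (counts >= 0, fraction in
#' [0, 1]) and assembles a state satisfying the sampled proportions:
#' `Q = (1 - f) S`, `A = f S`, the TAP total split equally across
#' compartments. A nonpositive sampled NSC total is resampled (at most 100
#' attempts).
#'
#' @param obs_means,obs_sds named vectors (`nsc_total`, `frac_active`,
#'   `tap_total`, `nb_total`) of means and SDs at the time origin.
#' @param params a [model_parameters()] object (for the compartment count).
#' @param seed optional RNG seed.
#' @return A [lineage_state()] vector.
#' @export
sample_initial_conditions <- function(obs_means, obs_sds, params,
                                      seed = NULL) {
  local_seed(seed)
  need <- c("nsc_total", "frac_active", "tap_total", "nb_total")
  stopifnot(all(need %in% names(obs_means)), all(need %in% names(obs_sds)))
  S <- 0
  for (attempt in seq_len(100)) {
    S <- rtnorm(1, obs_means[["nsc_total"]], obs_sds[["nsc_total"]], 0, Inf)
    if (S > 0) break
  }
  if (S <= 0) stop("could not sample a positive NSC total in 100 attempts")
  f <- rtnorm(1, obs_means[["frac_active"]], obs_sds[["frac_active"]], 0, 1)
  tap <- rtnorm(1, obs_means[["tap_total"]], obs_sds[["tap_total"]], 0, Inf)
  nb <- rtnorm(1, obs_means[["nb_total"]], obs_sds[["nb_total"]], 0, Inf)
  lineage_state(Q = (1 - f) * S, A = f * S,
                T = rep(tap / (params$n + 1), params$n + 1), N = nb)
}

## Per-(age, observable) data means and interpolated sigmas for a setting.
.likelihood_moments <- function(dataset, setting, variance_models) {
  sub <- dataset[dataset$setting %in% .setting_members(setting), ,
                 drop = FALSE]
  sub <- sub[sub$observable != "brdu_section", , drop = FALSE]
  g <- dataset_groups(sub)
  g$sigma <- NA_real_
  for (obs in unique(g$observable)) {
    vm <- variance_models[[obs]]
    if (is.null(vm)) vm <- fit_variance_decay(sub, obs)
    g$sigma[g$observable == obs] <- predict_sd(vm, g$age_days[
      g$observable == obs])
  }
  if (any(g$sigma <= 0)) stop("variance model produced nonpositive sigma")
  g
}

#' Gaussian negative log-likelihood with randomized initial conditions
#'
#' \deqn{f(\theta) = \sum_i \frac{(y_i^{model}(\theta) - \mu_i)^2}
#' {2 \sigma_i^2} + \sum_i \ln(\sigma_i \sqrt{2\pi}),}
#' where \eqn{\mu_i} are per-(age, observable) data means and
#' \eqn{\sigma_i} are interpolated by the variance-decay model;
#' measurements at different ages come from different mice and are treated
#' as independent. Because the initial state is sampled from its own
#' Gaussian distribution, the model trajectory is stochastic; `f` is
#' averaged over `n_ic_reps` initial-condition realizations (the
#' replicate-to-replicate spread is returned and is typically well below
#' 1%).
#'
#' @inheritParams wls_cost
#' @param n_ic_reps number of initial-condition realizations averaged.
#' @param seed RNG seed for the initial-condition draws.
#' @param ic_sds optional named vector of initial-condition SDs; defaults
#'   to the variance models evaluated at the first age.
#' @return List with `value` (the averaged `f`), `rep_values` and
#'   `spread` (SD of replicates / |mean|).
#' @export
neg_log_likelihood <- function(params, scenario, dataset, setting = "WT",
                               variance_models = NULL, n_ic_reps = 10,
                               seed = NULL, ic_sds = NULL,
                               rtol = 1e-6, atol = 1e-8) {
  validate_dataset(dataset)
  local_seed(seed)
  sub <- dataset[dataset$setting %in% .setting_members(setting), ,
                 drop = FALSE]
  variance_models <- variance_models %||% stats::setNames(
    lapply(c("nsc_total", "frac_active", "tap_total", "nb_total"),
           function(o) fit_variance_decay(sub, o)),
    c("nsc_total", "frac_active", "tap_total", "nb_total"))
  g <- .likelihood_moments(dataset, setting, variance_models)
  age0 <- min(g$age_days)
  ages <- sort(unique(g$age_days))

  at0 <- g[g$age_days == age0, , drop = FALSE]
  ic_means <- stats::setNames(at0$mean, at0$observable)
  if (is.null(ic_sds))
    ic_sds <- vapply(variance_models[names(ic_means)], predict_sd,
                     numeric(1), age_days = age0)
  names(ic_sds) <- names(ic_means)

  log_norm <- sum(log(g$sigma * sqrt(2 * pi)))
  rep_values <- vapply(seq_len(n_ic_reps), function(rep) {
    init <- sample_initial_conditions(ic_means, ic_sds, params)
    traj <- simulate_lineage(params, scenario, init,
                             sort(unique(c(age0, ages))),
                             rtol = rtol, atol = atol)
    idx <- match(g$age_days, traj$time_days)
    ymod <- mapply(function(i, obs) traj[[obs]][i], idx, g$observable)
    sum((ymod - g$mean)^2 / (2 * g$sigma^2)) + log_norm
  }, numeric(1))
  val <- mean(rep_values)
  list(value = val, rep_values = rep_values,
       spread = stats::sd(rep_values) / abs(val))
}

#' Adaptive Metropolis sampler
#'
#' Random-walk Metropolis whose proposal covariance adapts to the chain
#' history: after `adapt_start` iterations the proposal is
#' \eqn{N(0, s_d (\mathrm{cov}(history) + \epsilon I))} with
#' \eqn{s_d = 2.4^2 / d}. Proposals outside the box `bounds` are rejected
#' (the bounds double as flat priors; in lineage fits they also enforce the
#' finite range imposed on the weakly identified half-saturation constant
#' `K`). The chain is reproducible given `seed`.
#'
#' @param log_target function returning the log posterior density (finite
#'   at `init`).
#' @param init numeric start vector (typically the optimized estimate).
#' @param n_samples chain length.
#' @param bounds named list / 2-row matrix of `c(lower, upper)` per
#'   parameter; `NULL` for unbounded.
#' @param adapt_start iteration at which covariance adaptation begins.
#' @param eps covariance regularization.
#' @param cov0 initial proposal covariance; defaults to
#'   `1e-4 * diag(init^2)` (use the linearized covariance when available).
#' @param burn_in fraction of the chain discarded by downstream summaries.
#' @param seed RNG seed.
#' @return Object of class `"mcmc_chain"`: `samples` (n x d matrix),
#'   `log_post`, `acceptance_rate`, `config`.
#' @export
adaptive_metropolis <- function(log_target, init, n_samples,
                                bounds = NULL, adapt_start = 1000,
                                eps = 1e-10, cov0 = NULL, burn_in = 0.2,
                                seed = 1) {
  d <- length(init)
  nm <- names(init) %||% paste0("par", seq_len(d))
  if (!is.null(bounds)) {
    if (is.list(bounds)) bounds <- vapply(bounds[nm], identity, numeric(2))
    lo <- bounds[1, ]; hi <- bounds[2, ]
    if (any(init < lo | init > hi)) stop("init lies outside bounds")
  } else {
    lo <- rep(-Inf, d); hi <- rep(Inf, d)
  }
  f0 <- log_target(init)
  if (!is.finite(f0)) stop("log_target must be finite at init")
  if (is.null(cov0)) cov0 <- diag(pmax(1e-4 * init^2, 1e-12), d)
  sd_scale <- 2.4^2 / d

  set.seed(seed)
  samples <- matrix(NA_real_, n_samples, d, dimnames = list(NULL, nm))
  lp <- numeric(n_samples)
  x <- init; fx <- f0
  accepted <- 0L
  run_mean <- x
  run_cov <- matrix(0, d, d)
  chol_prop <- chol(cov0)
  for (i in seq_len(n_samples)) {
    if (i > adapt_start) {
      C <- sd_scale * (run_cov + eps * diag(d))
      ch <- tryCatch(chol(C), error = function(e) NULL)
      if (!is.null(ch)) chol_prop <- ch
    }
    prop <- x + drop(stats::rnorm(d) %*% chol_prop)
    if (all(prop >= lo & prop <= hi)) {
      fp <- log_target(prop)
      if (is.finite(fp) && log(stats::runif(1)) < fp - fx) {
        x <- prop; fx <- fp; accepted <- accepted + 1L
      }
    }
    samples[i, ] <- x
    lp[i] <- fx
    # recursive mean / covariance of the chain history
    delta <- x - run_mean
    run_mean <- run_mean + delta / i
    run_cov <- run_cov * ((i - 1) / i) +
      tcrossprod(delta, x - run_mean) / i
    if (i == 1000L && accepted == 0L)
      stop("no accepted moves in the first 1000 iterations; ",
           "rescale cov0 (e.g. shrink it) or recheck the target")
  }
  structure(list(samples = samples, log_post = lp,
                 acceptance_rate = accepted / n_samples,
                 config = list(adapt_start = adapt_start, eps = eps,
                               sd_scale = sd_scale, burn_in = burn_in,
                               seed = seed),
                 bounds = rbind(lower = lo, upper = hi)),
            class = "mcmc_chain")
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("Adaptive Metropolis chain: %d samples x %d parameters\n",
              nrow(x$samples), ncol(x$samples)))
  cat(sprintf("  acceptance rate %.3f, burn-in fraction %.2f\n",
              x$acceptance_rate, x$config$burn_in))
  invisible(x)
}

#' Post-burn-in samples of a chain
#'
#' @param chain an `"mcmc_chain"`.
#' @return Matrix of samples after discarding the burn-in fraction.
#' @export
chain_samples <- function(chain) {
  stopifnot(inherits(chain, "mcmc_chain"))
  drop_n <- floor(nrow(chain$samples) * chain$config$burn_in)
  chain$samples[(drop_n + 1):nrow(chain$samples), , drop = FALSE]
}

#' Store a chain as CSV plus JSON metadata
#'
#' @param chain an `"mcmc_chain"`.
#' @param path_csv per-iteration samples (one row per iteration).
#' @param path_json acceptance and configuration metadata.
#' @export
write_chain <- function(chain, path_csv, path_json = NULL) {
  df <- as.data.frame(chain$samples)
  df$log_post <- chain$log_post
  utils::write.csv(df, path_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(path_json)) {
    ess <- vapply(seq_len(ncol(chain$samples)), function(j) {
      v <- chain_samples(chain)[, j]
      acf1 <- stats::acf(v, plot = FALSE, lag.max = 100)$acf[-1]
      pos <- which(acf1 < 0)[1]
      tau <- 1 + 2 * sum(acf1[seq_len(if (is.na(pos)) 100 else pos - 1)])
      length(v) / max(tau, 1)
    }, numeric(1))
    jsonlite::write_json(
      list(acceptance_rate = chain$acceptance_rate, config = chain$config,
           effective_sample_size = stats::setNames(
             ess, colnames(chain$samples))),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path_csv)
}

#' Posterior-predictive trajectory ensemble
#'
#' For each draw, parameters are sampled from the post-burn-in chain and an
#' initial state from [sample_initial_conditions()]; the resulting
#' trajectories are summarized into per-time quantile bands for each
#' observable.
#'
#' @param chain an `"mcmc_chain"` whose columns name free model parameters.
#' @param scenario a [scenario()].
#' @param dataset the dataset the posterior was conditioned on (supplies
#'   initial-condition moments and the time span).
#' @param n_draws number of posterior draws (<= post-burn-in length).
#' @param base_params fixed parameter values for non-sampled slots.
#' @param setting experiment type.
#' @param variance_models per-observable variance models; fitted from the
#'   data when `NULL`.
#' @param ic_scale multiplier on the initial-condition SDs (0 freezes the
#'   initial state at the data means).
#' @param times output times; defaults to 60 points over the data span.
#' @param probs quantiles for the bands.
#' @param seed RNG seed.
#' @return List with `bands` (long data frame: time, observable, quantile,
#'   value) and `ensemble` (array draws x times x observables).
#' @export
posterior_predictive <- function(chain, scenario, dataset, n_draws = 100,
                                 base_params = default_parameters(),
                                 setting = "WT", variance_models = NULL,
                                 ic_scale = 1, times = NULL,
                                 probs = c(0.025, 0.5, 0.975), seed = 1) {
  sm <- chain_samples(chain)
  if (n_draws > nrow(sm))
    stop("n_draws exceeds the post-burn-in chain length")
  sub <- dataset[dataset$setting %in% .setting_members(setting), ,
                 drop = FALSE]
  obs_names <- c("nsc_total", "frac_active", "tap_total", "nb_total")
  variance_models <- variance_models %||% stats::setNames(
    lapply(obs_names, function(o) fit_variance_decay(sub, o)), obs_names)
  g <- .likelihood_moments(dataset, setting, variance_models)
  age0 <- min(g$age_days)
  at0 <- g[g$age_days == age0, , drop = FALSE]
  ic_means <- stats::setNames(at0$mean, at0$observable)
  ic_sds <- ic_scale * vapply(variance_models[names(ic_means)], predict_sd,
                              numeric(1), age_days = age0)
  names(ic_sds) <- names(ic_means)
  if (is.null(times)) times <- seq(age0, max(sub$age_days), length.out = 60)

  set.seed(seed)
  rows <- sample.int(nrow(sm), n_draws, replace = FALSE)
  ens <- array(NA_real_, c(n_draws, length(times), length(obs_names)),
               dimnames = list(NULL, NULL, obs_names))
  for (j in seq_len(n_draws)) {
    theta <- sm[rows[j], ]
    p <- update_params(base_params, as.list(theta))
    init <- sample_initial_conditions(ic_means, ic_sds, p)
    traj <- simulate_lineage(p, scenario, init, times,
                             rtol = 1e-6, atol = 1e-8)
    for (o in obs_names) ens[j, , o] <- traj[[o]]
  }
  bands <- do.call(rbind, lapply(obs_names, function(o) {
    q <- apply(ens[, , o, drop = FALSE], 2, stats::quantile, probs = probs)
    if (is.null(dim(q))) q <- matrix(q, nrow = 1)
    do.call(rbind, lapply(seq_along(probs), function(ip)
      data.frame(time_days = times, observable = o,
                 quantile = probs[ip], value = q[ip, ])))
  }))
  rownames(bands) <- NULL
  list(bands = bands, ensemble = ens)
}

#' Split-chain potential scale reduction factor
#'
#' Gelman--Rubin R-hat computed on split half-chains; values near 1
#' indicate the chains sample the same distribution. A convenience
#' diagnostic only — the package's workflow relies on acceptance rate and
#' effective sample size.
#'
#' @param chains a single `"mcmc_chain"`, a list of them, or a list of
#'   sample matrices with common columns.
#' @return Named vector of R-hat values, one per parameter.
#' @export
rhat <- function(chains) {
  if (inherits(chains, "mcmc_chain")) chains <- list(chains)
  mats <- lapply(chains, function(ch)
    if (inherits(ch, "mcmc_chain")) chain_samples(ch) else as.matrix(ch))
  # split each chain in half so a single chain still yields a diagnostic
  halves <- unlist(lapply(mats, function(m) {
    h <- floor(nrow(m) / 2)
    list(m[seq_len(h), , drop = FALSE],
         m[(h + 1):(2 * h), , drop = FALSE])
  }), recursive = FALSE)
  n <- nrow(halves[[1]])
  vapply(colnames(mats[[1]]), function(p) {
    draws <- sapply(halves, function(m) m[, p])
    mu <- colMeans(draws)
    W <- mean(apply(draws, 2, stats::var))
    B <- n * stats::var(mu)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}
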
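## Free / fixed parameter split per experiment type. Wild-type fits the four
## feedback constants; the knockout additionally frees the basal production
## r1 and the TAP division rate; chemotherapy fits are anchored on the
## wild-type parameters and free only what the treatment can change.
free_params_for_setting <- function(setting) {
  switch(setting,
         WT = c("r0", "K", "b0", "beta"),
         KO = c("r0", "r1", "K", "b0", "beta", "pT"),
         TMZ_young = c("pT", "d", "rho"),
         TMZ_old = c("r0", "pT", "d", "rho"),
         stop("no free-parameter set defined for setting ", setting))
}

#' Default box bounds for fitted parameters
#'
#' Used for multistart sampling and as optimizer bounds; start points are
#' drawn log-uniformly within them.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_bounds <- function() {
  list(r0 = c(1e-4, 10), r1 = c(0, 1e4), K = c(1, 1e5), b0 = c(1e-3, 1),
       beta = c(1e-6, 1), pT = c(0.05, 2), d = c(0, 10), rho = c(1, 1e3))
}

## Floors used when a bound's lower end is 0 but sampling/optimization is
## done on the log scale.
.log_floor <- c(r1 = 1e-2, d = 1e-3)

.setting_members <- function(setting) {
  switch(setting,
         TMZ_young = c("TMZ_young", "saline_young"),
         TMZ_old = c("TMZ_old", "saline_old"),
         setting)
}

.is_tmz <- function(setting) setting %in% c("TMZ_young", "TMZ_old")

## sigma^2 per (age, observable) group. A supplied variance model takes
## precedence for its observable; otherwise the cross-mouse variance where
## >= 2 mice with spread; otherwise a variance-decay interpolation fitted on
## the fly; otherwise the pooled per-observable variance (with a warning).
.group_sigma2 <- function(groups, dataset, variance_models) {
  s2 <- groups$var
  supplied <- groups$observable %in% names(variance_models)
  if (any(supplied)) {
    for (i in which(supplied))
      s2[i] <- predict_sd(variance_models[[groups$observable[i]]],
                          groups$age_days[i])^2
  }
  need <- !supplied & (is.na(s2) | s2 <= 0)
  if (any(need)) {
    for (i in which(need)) {
      obs <- groups$observable[i]
      vm <- tryCatch(suppressWarnings(fit_variance_decay(dataset, obs)),
                     error = function(e) NULL)
      if (!is.null(vm)) {
        s2[i] <- predict_sd(vm, groups$age_days[i])^2
        message(sprintf(
          "using variance-decay sigma for %s at age %g (single mouse)",
          obs, groups$age_days[i]))
      } else {
        pooled <- stats::var(dataset$value[dataset$observable == obs])
        if (!is.na(pooled) && pooled > 0) {
          s2[i] <- pooled
          warning(sprintf("pooled variance fallback for %s at age %g",
                          obs, groups$age_days[i]))
        } else {
          s2[i] <- 1
          warning(sprintf("unit variance fallback for %s at age %g",
                          obs, groups$age_days[i]))
        }
      }
    }
  }
  s2
}

## Model predictions matched to a dataset subset; returns a data frame with
## one row per datum: value, prediction, group id.
.predictions_for <- function(dataset, params, scenario, setting,
                             init = NULL, protocol = NULL,
                             rtol = 1e-6, atol = 1e-8) {
  sub <- dataset[dataset$setting %in% .setting_members(setting), ,
                 drop = FALSE]
  if (!nrow(sub)) stop("dataset has no records for setting ", setting)
  if (.is_tmz(setting)) {
    if (is.null(protocol)) stop("TMZ settings need a `protocol`")
    sub <- sub[sub$observable == "brdu_section", , drop = FALSE]
    if (is.null(init)) {
      init <- initial_state(params)
      attr(init, "age0") <- min(30, min(sub$age_days) - 1)
    }
    age0 <- attr(init, "age0") %||% min(sub$age_days)
    ages <- sort(unique(sub$age_days))
    times <- sort(unique(c(age0, ages)))
    traj <- simulate_tmz(protocol, params, scenario, init, times,
                         rtol = rtol, atol = atol)
    pred <- traj$brdu_total[match(sub$age_days, traj$time_days)]
    # section counts are scaled up to whole-region before residuals
    data.frame(age_days = sub$age_days, observable = sub$observable,
               value = sub$value * protocol$rho, prediction = pred,
               age0 = age0)
  } else {
    sub <- sub[sub$observable %in%
                 c("nsc_total", "frac_active", "tap_total", "nb_total"), ,
               drop = FALSE]
    if (is.null(init)) init <- initial_conditions_from_data(sub, params)
    age0 <- attr(init, "age0") %||% min(sub$age_days)
    ages <- sort(unique(sub$age_days))
    times <- sort(unique(c(age0, ages)))
    traj <- simulate_lineage(params, scenario, init, times,
                             rtol = rtol, atol = atol)
    idx <- match(sub$age_days, traj$time_days)
    pred <- mapply(function(i, obs) traj[[obs]][i], idx, sub$observable)
    data.frame(age_days = sub$age_days, observable = sub$observable,
               value = sub$value, prediction = pred, age0 = age0)
  }
}

## Weighted residual vector (r_i = (y_i - m_i)/sigma_j) plus bookkeeping.
.wls_parts <- function(dataset, params, scenario, setting, init = NULL,
                       protocol = NULL, variance_models = NULL,
                       rtol = 1e-6, atol = 1e-8) {
  pr <- .predictions_for(dataset, params, scenario, setting, init, protocol,
                         rtol, atol)
  sub <- data.frame(setting = setting, mouse_id = NA_character_,
                    age_days = pr$age_days, observable = pr$observable,
                    value = pr$value)
  groups <- dataset_groups(sub)
  key <- paste(pr$age_days, pr$observable)
  gkey <- paste(groups$age_days, groups$observable)
  s2 <- .group_sigma2(groups, sub, variance_models)
  w <- 1 / s2[match(key, gkey)]
  resid <- (pr$value - pr$prediction) * sqrt(w)
  list(residuals = resid, E = sum(resid^2), n = nrow(pr),
       predictions = pr, sigma2 = s2, groups = groups)
}

## Precomputed objective closure used by the multistart fitter: dataset
## subsetting, weighting and time grids are resolved once, so each cost
## evaluation is essentially one ODE solve.
.make_wls_objective <- function(dataset, scenario, setting, base_params,
                                base_protocol = NULL, init = NULL,
                                variance_models = NULL,
                                weighting = "smoothed",
                                rtol = 1e-6, atol = 1e-8) {
  sub <- dataset[dataset$setting %in% .setting_members(setting), ,
                 drop = FALSE]
  if (!nrow(sub)) stop("dataset has no records for setting ", setting)
  n <- base_params$n

  if (.is_tmz(setting)) {
    sub <- sub[sub$observable == "brdu_section", , drop = FALSE]
    if (is.null(init)) {
      init <- initial_state(base_params)
      attr(init, "age0") <- min(30, min(sub$age_days) - 1)
    }
    age0 <- attr(init, "age0") %||% min(sub$age_days)
    times <- sort(unique(c(age0, sub$age_days)))
    grp <- match(sub$age_days, sort(unique(sub$age_days)))
    var_y <- tapply(sub$value, grp, stats::var)[grp]
    pooled <- stats::var(sub$value)
    var_y[is.na(var_y) | var_y <= 0] <- if (is.finite(pooled) && pooled > 0)
      pooled else 1
    cost <- function(params, protocol) {
      traj <- simulate_tmz(protocol, params, scenario, init, times,
                           rtol = rtol, atol = atol)
      pred <- traj$brdu_total[match(sub$age_days, traj$time_days)]
      # scale section data up by rho; sigma^2 scales by rho^2
      sum((sub$value * protocol$rho - pred)^2 /
            (protocol$rho^2 * var_y))
    }
    resid <- function(params, protocol) {
      traj <- simulate_tmz(protocol, params, scenario, init, times,
                           rtol = rtol, atol = atol)
      pred <- traj$brdu_total[match(sub$age_days, traj$time_days)]
      (sub$value * protocol$rho - pred) / sqrt(protocol$rho^2 * var_y)
    }
    return(list(cost = cost, resid = resid, n = nrow(sub), init = init))
  }

  sub <- sub[sub$observable %in%
               c("nsc_total", "frac_active", "tap_total", "nb_total"), ,
             drop = FALSE]
  if (is.null(init)) init <- initial_conditions_from_data(sub, base_params)
  age0 <- attr(init, "age0") %||% min(sub$age_days)
  times <- sort(unique(c(age0, sub$age_days)))
  if (weighting == "smoothed") {
    # interpolated sigma(t) per observable: stable weights at 2-6 mice/age
    vms <- variance_models %||% list()
    sig_row <- rep(NA_real_, nrow(sub))
    for (o in unique(sub$observable)) {
      vm <- vms[[o]] %||% suppressWarnings(
        tryCatch(fit_variance_decay(sub, o), error = function(e) NULL))
      rows <- sub$observable == o
      if (!is.null(vm)) sig_row[rows] <- predict_sd(vm, sub$age_days[rows])
    }
    if (any(is.na(sig_row) | sig_row <= 0)) weighting <- "empirical"
    else w_row <- 1 / sig_row^2
  }
  if (weighting == "empirical") {
    groups <- dataset_groups(sub)
    s2 <- suppressMessages(.group_sigma2(groups, sub, variance_models))
    w_row <- 1 / s2[match(paste(sub$age_days, sub$observable),
                          paste(groups$age_days, groups$observable))]
  }
  idx_time <- match(sub$age_days, times)
  tap_cols <- paste0("T", 0:n)
  obs_idx <- match(sub$observable,
                   c("nsc_total", "frac_active", "tap_total", "nb_total"))
  predict_rows <- function(params) {
    out <- .integrate(init, times, params, scenario, 0, "lsoda", rtol, atol)
    nsc <- out[, "Q"] + out[, "A"]
    pred_mat <- cbind(nsc,
                      ifelse(nsc > 0, out[, "A"] / nsc, 0),
                      rowSums(out[, tap_cols, drop = FALSE]),
                      out[, "N"])
    pred_mat[cbind(idx_time, obs_idx)]
  }
  list(cost = function(params, protocol = NULL)
         sum(w_row * (sub$value - predict_rows(params))^2),
       resid = function(params, protocol = NULL)
         (sub$value - predict_rows(params)) * sqrt(w_row),
       n = nrow(sub), init = init)
}

#' Weighted least-squares cost of a parameter set
#'
#' The cost is
#' \deqn{E = \sum_j \frac{1}{\sigma_j^2} \sum_i (y_i^{data} - y_i^{model})^2,}
#' summed over time points `j` (for each observable) and the mice measured
#' at `j`; \eqn{\sigma_j^2} is the cross-mouse variance at that age and
#' observable. Time points with a single mouse (or no spread) fall back to
#' the variance-decay interpolation (see [fit_variance_decay()]); for
#' chemotherapy settings, section-level BrdU counts are scaled up by `rho`
#' to whole-region scale before the residuals are formed.
#'
#' @param dataset a longitudinal dataset (see [validate_dataset()]).
#' @param params candidate [model_parameters()].
#' @param scenario a [scenario()].
#' @param setting experiment type: `"WT"`, `"KO"`, `"TMZ_young"` or
#'   `"TMZ_old"` (TMZ settings also use their saline baselines).
#' @param init optional initial state (default derived from the data).
#' @param protocol a [tmz_protocol()]; required for TMZ settings.
#' @param variance_models optional named list (per observable) of variance
#'   models from [fit_variance_decay()]; when supplied they define
#'   \eqn{\sigma_j} for their observables, otherwise the empirical
#'   cross-mouse variances are used.
#' @param rtol,atol integrator tolerances used during fitting.
#' @return The scalar cost `E >= 0`.
#' @export
wls_cost <- function(dataset, params, scenario, setting = "WT", init = NULL,
                     protocol = NULL, variance_models = NULL,
                     rtol = 1e-6, atol = 1e-8) {
  validate_dataset(dataset)
  .wls_parts(dataset, params, scenario, setting, init, protocol,
             variance_models, rtol, atol)$E
}

## Assemble (params, protocol) from a named free-parameter vector.
.apply_theta <- function(theta, base_params, base_protocol, setting) {
  model_names <- intersect(names(theta),
                           c("r0", "r1", "K", "b0", "beta", "pA", "pT",
                             "delta"))
  if (.is_tmz(setting)) {
    post <- update_params(base_params, as.list(theta[model_names]))
    protocol <- tmz_protocol(
      treatment_age = base_protocol$treatment_age,
      d = unname(theta[["d"]] %||% base_protocol$d),
      rho = unname(theta[["rho"]] %||% base_protocol$rho),
      window = base_protocol$window,
      post_params = post)
    list(params = base_params, protocol = protocol)
  } else {
    list(params = update_params(base_params, as.list(theta[model_names])),
         protocol = NULL)
  }
}

#' Multistart weighted least-squares fit
#'
#' Minimizes [wls_cost()] over the free parameters of the given setting
#' (wild type: `r0, K, b0, beta`; knockout: `r0, r1, K, b0, beta, pT`;
#' TMZ young: `pT, d, rho`; TMZ old: `r0, pT, d, rho`). Start points are
#' drawn log-uniformly within the bounds; the cost is evaluated at every
#' start and the `n_refine` most promising starts are polished with a
#' bound-constrained quasi-Newton optimizer (`L-BFGS-B` on the log10 scale).
#' The start reaching the smallest cost wins; exact ties (to 1e-10) go to
#' the lowest start index, so results are reproducible given `seed`.
#'
#' @inheritParams wls_cost
#' @param base_params fixed parameter values (the non-free slots); for TMZ
#'   settings these are the wild-type estimates.
#' @param n_starts number of multistart samples.
#' @param n_refine number of best starts polished by local optimization.
#' @param seed RNG seed controlling start sampling.
#' @param bounds named list of `c(lower, upper)`; defaults to
#'   [default_bounds()].
#' @param base_protocol a [tmz_protocol()] carrying treatment age and window
#'   (required for TMZ settings; its `d`, `rho`, `post_params` are fitted).
#' @param weighting `"smoothed"` (default) weights residuals by the fitted
#'   variance-decay model \eqn{\sigma(t)} of each observable — with a
#'   handful of mice per age the raw per-age variances make noisy,
#'   heavy-tailed weights, and the smoothed \eqn{\sigma(t)} is the same
#'   interpolation the Bayesian likelihood uses; `"empirical"` uses the raw
#'   per-age cross-mouse variances of [wls_cost()].
#' @param maxit maximum local-optimizer iterations.
#' @return Object of class `"lineage_fit"`: fitted parameters, cost `E`,
#'   residual count `n`, free-parameter count `k`, the winning start index,
#'   a per-start summary, and the assembled full parameter set (and
#'   protocol, for TMZ).
#' @export
fit_multistart <- function(dataset, scenario, setting = "WT",
                           base_params = default_parameters(),
                           n_starts = 500, n_refine = 25, seed = 1,
                           bounds = NULL, base_protocol = NULL, init = NULL,
                           variance_models = NULL,
                           weighting = c("smoothed", "empirical"),
                           rtol = 1e-6, atol = 1e-8, maxit = 200) {
  weighting <- match.arg(weighting)
  validate_dataset(dataset)
  free <- free_params_for_setting(setting)
  bounds <- utils::modifyList(default_bounds(), bounds %||% list())
  bounds <- bounds[free]
  if (.is_tmz(setting) && is.null(base_protocol))
    stop("TMZ settings need `base_protocol`")

  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  lo_log <- log10(pmax(lo, ifelse(free %in% names(.log_floor),
                                  .log_floor[free], lo)))
  lo_log[!is.finite(lo_log)] <- log10(.log_floor[free[!is.finite(lo_log)]])
  hi_log <- log10(hi)

  obj <- .make_wls_objective(dataset, scenario, setting, base_params,
                             base_protocol, init, variance_models,
                             weighting, rtol, atol)
  cost_nat <- function(theta) {
    names(theta) <- free
    ap <- .apply_theta(theta, base_params, base_protocol, setting)
    tryCatch(obj$cost(ap$params, ap$protocol), error = function(e) Inf)
  }
  cost_log <- function(x) cost_nat(10^x)

  set.seed(seed)
  starts <- sapply(seq_along(free), function(j)
    stats::runif(n_starts, lo_log[j], hi_log[j]))
  if (n_starts == 1) starts <- matrix(starts, nrow = 1)
  colnames(starts) <- free

  E0 <- suppressMessages(apply(starts, 1, cost_log))
  refine_idx <- order(E0)[seq_len(min(n_refine, n_starts))]
  results <- lapply(refine_idx, function(i) {
    opt <- tryCatch(
      suppressMessages(suppressWarnings(
        stats::optim(starts[i, ], cost_log, method = "L-BFGS-B",
                     lower = lo_log, upper = hi_log,
                     control = list(maxit = maxit, factr = 1e9)))),
      error = function(e) list(par = starts[i, ], value = E0[i],
                               convergence = 99))
    list(index = i, par = opt$par, E = opt$value,
         converged = opt$convergence == 0)
  })
  if (all(!vapply(results, function(r) is.finite(r$E), logical(1))))
    stop("all multistart optimizations failed to produce a finite cost")

  Es <- vapply(results, `[[`, numeric(1), "E")
  tied <- which(Es <= min(Es) + 1e-10)
  best <- results[[tied[which.min(vapply(results[tied], `[[`, numeric(1),
                                         "index"))]]]
  theta <- stats::setNames(10^best$par, free)
  ap <- .apply_theta(theta, base_params, base_protocol, setting)

  starts_summary <- data.frame(
    start = seq_len(n_starts), E_start = E0,
    E_refined = NA_real_)
  starts_summary$E_refined[refine_idx] <- Es

  fixed_names <- setdiff(c("r0", "r1", "K", "b0", "beta", "pA", "pT",
                           "delta", "n", "NSC0"), free)
  structure(list(
    scenario = scenario$name, setting = setting,
    par = theta, fixed = unclass(base_params)[fixed_names],
    E = best$E, n = obj$n,
    k = length(free), start_index = best$index,
    starts = starts_summary, params = ap$params, protocol = ap$protocol,
    bounds = bounds, seed = seed, init = obj$init,
    variance_models = variance_models, weighting = weighting,
    dataset = dataset, rtol = rtol, atol = atol),
    class = "lineage_fit")
}

#' @export
print.lineage_fit <- function(x, ...) {
  cat(sprintf("WLS fit: scenario %s, setting %s\n", x$scenario, x$setting))
  cat(sprintf("  E = %.6g over n = %d residuals, k = %d free parameters\n",
              x$E, x$n, x$k))
  cat("  estimates:\n")
  for (nm in names(x$par)) cat(sprintf("    %-5s = %.6g\n", nm, x$par[nm]))
  invisible(x)
}

#' Linearized covariance of a fit
#'
#' Finite-difference Jacobian `J` of the weighted residual vector at the
#' estimate; the parameter covariance is the generalized inverse of
#' `t(J) %*% J`. Square roots of the diagonal are the standard deviations;
#' off-diagonal entries give the parameter correlations. A rank-deficient
#' Jacobian triggers a warning naming the (numerically) unidentifiable
#' directions, and the Moore-Penrose pseudo-inverse is used.
#'
#' @param fit a `"lineage_fit"` from [fit_multistart()].
#' @param rel_step relative finite-difference step.
#' @return List with `covariance`, `std`, `correlation` (all named by the
#'   free parameters).
#' @export
linearized_covariance <- function(fit, rel_step = 1e-5) {
  stopifnot(inherits(fit, "lineage_fit"))
  free <- names(fit$par)
  obj <- .make_wls_objective(fit$dataset, scenario(fit$scenario),
                             fit$setting, fit$params, fit$protocol,
                             fit$init, fit$variance_models,
                             fit$weighting %||% "smoothed",
                             fit$rtol, fit$atol)
  resid_fun <- function(theta) {
    names(theta) <- free
    ap <- .apply_theta(theta, fit$params, fit$protocol, fit$setting)
    obj$resid(ap$params, ap$protocol)
  }
  J <- num_jacobian(resid_fun, fit$par, h = pmax(rel_step * abs(fit$par),
                                                 1e-10))
  colnames(J) <- free
  .covariance_from_jacobian(J)
}

## Covariance of parameter estimates from the Jacobian of the weighted
## residual vector, via the generalized inverse of J'J; warns about
## numerically unidentifiable directions when J is rank deficient.
.covariance_from_jacobian <- function(J) {
  free <- colnames(J) %||% paste0("par", seq_len(ncol(J)))
  sv <- svd(J)
  if (min(sv$d) < 1e-8 * max(sv$d)) {
    null_dirs <- free[apply(abs(sv$v[, sv$d < 1e-8 * max(sv$d),
                                     drop = FALSE]),
                            2, which.max)]
    warning("residual Jacobian is rank deficient; weakly identified ",
            "direction(s) involve: ", paste(null_dirs, collapse = ", "))
  }
  covar <- MASS::ginv(crossprod(J))
  dimnames(covar) <- list(free, free)
  std <- sqrt(pmax(diag(covar), 0))
  corr <- covar / outer(std, std)
  diag(corr) <- 1
  list(covariance = covar, std = stats::setNames(std, free),
       correlation = corr)
}

#' Serialize a fit to JSON (with provenance)
#'
#' @param fit a `"lineage_fit"`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    scenario = fit$scenario, setting = fit$setting,
    estimates = as.list(fit$par), fixed = fit$fixed,
    E = fit$E, n = fit$n, k = fit$k, start_index = fit$start_index,
    seed = fit$seed, bounds = fit$bounds,
    software = as.character(utils::packageVersion("nscfeedback")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
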
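obs4 <- c("nsc_total", "frac_active", "tap_total", "nb_total")

test_that("the variance-decay curve evaluates and recovers known constants", {
  vm <- structure(list(d0 = 50, d1 = 200, d3 = 0.01, t0 = 30,
                       observable = "nsc_total"),
                  class = "variance_model")
  expect_equal(predict_sd(vm, 30), 250)          # sigma(0) = d0 + d1
  expect_lt(abs(predict_sd(vm, 3000) - 50), 1e-8)  # -> d0 at late ages

  # exact per-age SDs planted in the data: two mice at mean +/- s/sqrt(2)
  # have sample SD exactly s... (factor sqrt(2)/sqrt(2)); here mean +/- s
  # gives sample SD s * sqrt(2), so plant s / sqrt(2) offsets
  true <- list(d0 = 40, d1 = 160, d3 = 0.012)
  ages <- seq(30, 600, length.out = 9)
  ds <- do.call(rbind, lapply(ages, function(a) {
    s <- true$d0 + true$d1 * exp(-true$d3 * (a - 30))
    data.frame(setting = "WT", mouse_id = c("m1", "m2"), age_days = a,
               observable = "nsc_total",
               value = 1000 + c(-1, 1) * s / sqrt(2))
  }))
  vm2 <- fit_variance_decay(ds, "nsc_total")
  expect_lt(abs(vm2$d0 - true$d0) / true$d0, 0.05)
  expect_lt(abs(vm2$d1 - true$d1) / true$d1, 0.05)
  expect_lt(abs(vm2$d3 - true$d3) / true$d3, 0.05)

  # insufficient replication falls back to a pooled constant sigma
  one <- make_dataset(list(list(age = 50, observable = "nb_total",
                                values = c(10, 30)),
                           list(age = 90, observable = "nb_total",
                                values = c(20, 28))))
  expect_warning(vm3 <- fit_variance_decay(one, "nb_total"), "pooled")
  expect_equal(vm3$d1, 0)
})

test_that("initial-condition sampling honours the observed proportions", {
  p <- default_parameters()
  means <- c(nsc_total = 1900, frac_active = 0.3, tap_total = 5000,
             nb_total = 23000)
  zero <- means * 0
  st <- sample_initial_conditions(means, zero, p)
  expect_equal(state_observables(st), means)     # exact round trip
  expect_equal(st[["Q"]], 0.7 * 1900)
  expect_equal(unname(st[paste0("T", 0:3)]), rep(1250, 4))

  sds <- c(nsc_total = 250, frac_active = 0.05, tap_total = 800,
           nb_total = 3000)
  set.seed(21)
  draws <- t(replicate(5000, state_observables(
    sample_initial_conditions(means, sds, p))))
  for (o in obs4) {
    se <- sd(draws[, o]) / sqrt(nrow(draws))
    expect_lt(abs(mean(draws[, o]) - means[[o]]), 3.5 * se + 0.01 * sds[[o]])
  }
  expect_true(all(draws >= 0))
  expect_true(all(draws[, "frac_active"] <= 1))
})

test_that("the Gaussian likelihood collapses to its normalization at a perfect fit", {
  p <- default_parameters()
  sc <- wt_scenario()
  ages <- c(30, 100, 300, 700)
  init <- initial_state(p, f0 = 0.3, tap_total = 5000, nb_total = 23000)
  traj <- simulate_lineage(p, sc, init, ages)
  ds <- do.call(rbind, lapply(seq_along(ages), function(i)
    do.call(rbind, lapply(obs4, function(o)
      data.frame(setting = "WT", mouse_id = c("m1", "m2"),
                 age_days = ages[i], observable = o,
                 value = rep(traj[[o]][i], 2))))))
  vms <- stats::setNames(lapply(obs4, function(o) const_vm(5, o)), obs4)
  nll <- neg_log_likelihood(p, sc, ds, "WT", variance_models = vms,
                            n_ic_reps = 3, seed = 1,
                            ic_sds = c(nsc_total = 0, frac_active = 0,
                                       tap_total = 0, nb_total = 0))
  n_groups <- 4 * length(ages)
  expect_equal(nll$value, n_groups * log(5 * sqrt(2 * pi)),
               tolerance = 1e-6)
  expect_lt(nll$spread, 1e-10)  # deterministic initial conditions

  # doubling every sigma adds sum(log 2) and quarters the quadratic part
  vms2 <- stats::setNames(lapply(obs4, function(o) const_vm(10, o)), obs4)
  ds_noisy <- ds
  set.seed(2)
  ds_noisy$value <- ds_noisy$value * (1 + rnorm(nrow(ds), 0, 0.05))
  f1 <- neg_log_likelihood(p, sc, ds_noisy, "WT", variance_models = vms,
                           n_ic_reps = 1, seed = 3,
                           ic_sds = c(nsc_total = 0, frac_active = 0,
                                      tap_total = 0, nb_total = 0))$value
  f2 <- neg_log_likelihood(p, sc, ds_noisy, "WT", variance_models = vms2,
                           n_ic_reps = 1, seed = 3,
                           ic_sds = c(nsc_total = 0, frac_active = 0,
                                      tap_total = 0, nb_total = 0))$value
  L1 <- n_groups * log(5 * sqrt(2 * pi))
  quad <- f1 - L1
  expect_equal(f2, f1 + n_groups * log(2) - 0.75 * quad, tolerance = 1e-6)

  # randomized initial conditions: replicate spread stays modest (the
  # 25% initial-condition scatter feeds a slowly contracting system)
  cfg <- generator_config(sc, ages = log_spaced_ages(8), seed = 3)
  dsn <- generate_dataset(cfg)
  nll2 <- neg_log_likelihood(p, sc, dsn, "WT", n_ic_reps = 10, seed = 4)
  expect_lt(nll2$spread, 0.1)
  expect_length(nll2$rep_values, 10)
})

test_that("the adaptive sampler is reproducible and calibrated on a Gaussian", {
  lt <- function(x) -sum(x^2) / 2
  b <- list(x = c(-10, 10), y = c(-10, 10))
  c1 <- adaptive_metropolis(lt, c(x = 0.3, y = -0.2), 4000, bounds = b,
                            cov0 = diag(0.5, 2), seed = 8)
  c2 <- adaptive_metropolis(lt, c(x = 0.3, y = -0.2), 4000, bounds = b,
                            cov0 = diag(0.5, 2), seed = 8)
  expect_identical(c1$samples, c2$samples)
  expect_gt(c1$acceptance_rate, 0.1)
  expect_lt(c1$acceptance_rate, 0.6)
  sm <- chain_samples(c1)
  expect_lt(max(abs(colMeans(sm))), 0.15)
  expect_true(all(sm >= -10 & sm <= 10))

  # hopeless initial proposal scale aborts with advice
  expect_error(
    adaptive_metropolis(lt, c(x = 0, y = 0), 2000,
                        bounds = list(x = c(-1, 1), y = c(-1, 1)),
                        cov0 = diag(1e8, 2), adapt_start = 5000, seed = 1),
    "rescale")
  expect_error(adaptive_metropolis(lt, c(x = 99, y = 0), 100,
                                   bounds = b, seed = 1),
               "outside bounds")
})

test_that("posterior-predictive bands behave under degenerate and shrinking inputs", {
  p <- default_parameters()
  sc <- wt_scenario()
  cfg <- generator_config(sc, ages = c(30, 120, 400, 700),
                          mice_per_age = 3, seed = 6)
  ds <- generate_dataset(cfg)

  # a chain stuck at one point plus frozen initial conditions -> width 0
  one <- matrix(rep(c(r0 = 0.2, K = 1000, b0 = 0.52, beta = 7.3e-5),
                    each = 50), nrow = 50)
  colnames(one) <- c("r0", "K", "b0", "beta")
  chain <- structure(list(samples = one, log_post = rep(0, 50),
                          acceptance_rate = 0.3,
                          config = list(burn_in = 0.2, adapt_start = 10,
                                        eps = 1e-10, sd_scale = 2.88,
                                        seed = 1),
                          bounds = NULL),
                     class = "mcmc_chain")
  pp0 <- posterior_predictive(chain, sc, ds, n_draws = 10, ic_scale = 0,
                              seed = 2)
  width0 <- with(subset(pp0$bands, observable == "nsc_total"),
                 tapply(value, time_days, function(v) diff(range(v))))
  expect_lt(max(width0), 1e-6)

  pp1 <- posterior_predictive(chain, sc, ds, n_draws = 20, ic_scale = 1,
                              seed = 2)
  pp_half <- posterior_predictive(chain, sc, ds, n_draws = 20,
                                  ic_scale = 0.5, seed = 2)
  w1 <- with(subset(pp1$bands, observable == "nsc_total" &
                      quantile %in% c(0.025, 0.975)),
             tapply(value, time_days, function(v) diff(range(v))))
  wh <- with(subset(pp_half$bands, observable == "nsc_total" &
                      quantile %in% c(0.025, 0.975)),
             tapply(value, time_days, function(v) diff(range(v))))
  expect_lt(mean(wh), mean(w1))

  expect_error(posterior_predictive(chain, sc, ds, n_draws = 1000),
               "exceeds")
})

test_that("posteriors concentrate on the self-renewal constants, not on K", {
  sc <- wt_scenario()
  ds <- generate_dataset(generator_config(sc, ages = log_spaced_ages(8),
                                          mice_per_age = 4, seed = 2))
  base <- default_parameters()
  vms <- stats::setNames(lapply(obs4, function(o) fit_variance_decay(ds, o)),
                         obs4)
  fit <- fit_multistart(ds, sc, "WT", n_starts = 60, n_refine = 6,
                        seed = 31)
  init <- fit$par
  target <- function(theta) {
    names(theta) <- names(init)
    p <- nscfeedback:::update_params(base, as.list(theta))
    -neg_log_likelihood(p, sc, ds, "WT", variance_models = vms,
                        n_ic_reps = 2, seed = 1)$value
  }
  f0 <- target(init)
  sig0 <- vapply(seq_along(init), function(i) {
    th <- init; delta <- 5e-3 * th[i]; th[i] <- th[i] + delta
    delta / sqrt(2 * max(abs(target(th) - f0), 0.5))
  }, numeric(1))
  chain <- adaptive_metropolis(target, init, 6000,
                               bounds = default_bounds()[names(init)],
                               cov0 = diag(sig0^2), seed = 77)
  sm <- chain_samples(chain)
  rel_iqr <- apply(sm, 2, function(v)
    diff(quantile(v, c(0.25, 0.75))) / abs(median(v)))
  expect_lt(rel_iqr[["b0"]], 0.5)
  expect_lt(rel_iqr[["beta"]], 0.5)
  expect_gt(rel_iqr[["K"]], rel_iqr[["b0"]])
  expect_gt(chain$acceptance_rate, 0.01)
})

test_that("the scale-reduction diagnostic is near one for matched chains", {
  lt <- function(x) -sum(x^2) / 2
  b <- list(x = c(-10, 10), y = c(-10, 10))
  chains <- lapply(c(3, 4), function(s)
    adaptive_metropolis(lt, c(x = 0.1, y = 0), 4000, bounds = b,
                        cov0 = diag(0.5, 2), seed = s))
  r <- rhat(chains)
  expect_true(all(r < 1.1))
  # chains stuck in different places are flagged
  off <- chains
  off[[2]]$samples <- off[[2]]$samples + 5
  expect_gt(max(rhat(off)), 1.5)
})
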
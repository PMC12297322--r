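test_that("the weighted cost is zero at a perfect fit and matches hand values", {
  p <- default_parameters()
  sc <- wt_scenario()
  init <- initial_state(p, f0 = 0.3, tap_total = 5000, nb_total = 23000)
  ages <- c(30, 100, 300, 700)
  traj <- simulate_lineage(p, sc, init, ages)

  # two identical mice exactly on the trajectory -> E = 0
  rows <- list()
  for (o in c("nsc_total", "frac_active", "tap_total", "nb_total"))
    rows[[o]] <- NULL
  ds <- do.call(rbind, lapply(seq_along(ages), function(i)
    do.call(rbind, lapply(c("nsc_total", "frac_active", "tap_total",
                            "nb_total"), function(o)
      data.frame(setting = "WT", mouse_id = c("m1", "m2"),
                 age_days = ages[i], observable = o,
                 value = rep(traj[[o]][i], 2))))))
  vms <- lapply(c(nsc_total = 1, frac_active = 2, tap_total = 3,
                  nb_total = 4),
                function(i) const_vm(10, "x"))
  names(vms) <- c("nsc_total", "frac_active", "tap_total", "nb_total")
  # zero up to the fitting-grade integrator tolerance
  expect_lt(wls_cost(ds, p, sc, init = init, variance_models = vms), 1e-3)

  # hand value: one time point, data {1, 3}, model value 2, sigma^2 = 1
  # (checked on the neuroblast observable, whose prediction we pin by
  # a two-point dataset carrying the model value at the anchor age)
  ds2 <- make_dataset(list(
    list(age = 100, observable = "nb_total", values = c(1, 3))))
  parts <- nscfeedback:::.wls_parts(
    ds2, p, sc, "WT",
    init = {
      s <- initial_state(p, f0 = 0.3); attr(s, "age0") <- 100; s
    },
    variance_models = list(nb_total = const_vm(1, "nb_total")))
  pred <- parts$predictions$prediction[1]
  expect_equal(parts$E, (1 - pred)^2 + (3 - pred)^2, tolerance = 1e-10)

  # weighting scales as 1/sigma^2: doubling sigma quarters the cost, so
  # a common rescaling of residuals and sigma leaves E unchanged
  ds3 <- make_dataset(list(
    list(age = 30, observable = "nb_total", values = c(800, 1200)),
    list(age = 200, observable = "nb_total", values = c(300, 500))))
  E_sig <- wls_cost(ds3, p, sc, init = init,
                    variance_models = list(nb_total = const_vm(100,
                                                               "nb_total")))
  E_2sig <- wls_cost(ds3, p, sc, init = init,
                     variance_models = list(nb_total = const_vm(200,
                                                                "nb_total")))
  expect_equal(E_sig / 4, E_2sig, tolerance = 1e-10)
})

test_that("multistart fitting is deterministic and the winner is the best start", {
  sc <- wt_scenario()
  cfg <- generator_config(sc, ages = c(30, 80, 200, 450, 700),
                          mice_per_age = 3, seed = 5)
  ds <- generate_dataset(cfg)
  f1 <- fit_multistart(ds, sc, "WT", n_starts = 12, n_refine = 4, seed = 9)
  f2 <- fit_multistart(ds, sc, "WT", n_starts = 12, n_refine = 4, seed = 9)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$E, f2$E)
  expect_identical(f1$start_index, f2$start_index)

  expect_lte(f1$E, min(f1$starts$E_start, na.rm = TRUE) + 1e-10)
  expect_lte(f1$E, min(f1$starts$E_refined, na.rm = TRUE) + 1e-10)
  expect_equal(f1$k, 4L)
  expect_equal(f1$n, nrow(ds))

  # starting at the truth with a single start stays at or under the
  # truth's cost
  truth <- attr(ds, "truth")$params
  E_truth <- nscfeedback:::.make_wls_objective(
    ds, sc, "WT", default_parameters())$cost(
      nscfeedback:::update_params(default_parameters(),
                                  truth[c("r0", "K", "b0", "beta")]))
  expect_lte(f1$E, E_truth + 1e-8)
})

test_that("covariance from the residual Jacobian matches the normal equations", {
  # weighted linear model oracle: r(theta) = sqrt(W) (y - X theta);
  # covariance must equal (X' W X)^(-1)
  set.seed(3)
  X <- cbind(1, rnorm(12), runif(12))
  w <- runif(12, 0.5, 2)
  J <- -sqrt(w) * X
  colnames(J) <- c("a", "b", "c")
  got <- nscfeedback:::.covariance_from_jacobian(J)
  expect_equal(got$covariance, solve(t(X) %*% diag(w) %*% X),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(diag(got$correlation)), rep(1, 3))
  expect_true(all(abs(got$correlation) <= 1 + 1e-12))

  # rank deficiency is reported with the offending direction
  J2 <- cbind(J[, 1], J[, 1], J[, 3])
  colnames(J2) <- c("a", "b", "c")
  expect_warning(nscfeedback:::.covariance_from_jacobian(J2),
                 "rank deficient")
})

test_that("fit covariance reproduces the self-renewal correlation structure", {
  sc <- wt_scenario()
  cfg <- generator_config(sc, ages = log_spaced_ages(8), mice_per_age = 4,
                          seed = 2)
  ds <- generate_dataset(cfg)
  fit <- fit_multistart(ds, sc, "WT", n_starts = 40, n_refine = 6,
                        seed = 11)
  cv <- linearized_covariance(fit)
  expect_true(isSymmetric(cv$covariance, tol = 1e-8))
  expect_true(all(eigen(cv$covariance, only.values = TRUE)$values > -1e-8))
  # b0 and beta strongly correlated; r0 and b0 much less so
  expect_gt(abs(cv$correlation["b0", "beta"]), 0.5)
  expect_gt(abs(cv$correlation["b0", "beta"]),
            abs(cv$correlation["r0", "b0"]))
})

test_that("chemotherapy fits recover the slowed TAP division rate", {
  wt <- default_parameters()
  sc <- wt_scenario()
  post <- nscfeedback:::update_params(wt, list(pT = 0.324))
  proto <- tmz_protocol(treatment_age = 60, d = 1, rho = 50, window = 3,
                        post_params = post)
  cfg <- generator_config(sc, setting = "TMZ_young", protocol = proto,
                          mice_per_age = 4, seed = 7)
  ds <- generate_tmz_dataset(cfg)
  fit <- fit_multistart(ds, sc, "TMZ_young", base_params = wt,
                        base_protocol = tmz_protocol(60, d = 1, rho = 1,
                                                     window = 3),
                        n_starts = 60, n_refine = 6, seed = 5)
  expect_lt(fit$par[["pT"]], wt$pT)     # slower cycling after treatment
  expect_gt(fit$par[["rho"]], 10)        # section-to-region scale recovered
  expect_lt(abs(fit$par[["rho"]] - 50) / 50, 0.5)
})
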
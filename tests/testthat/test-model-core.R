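test_that("feedback rates follow the Hill forms", {
  p <- unit_params()
  s <- lineage_state(Q = 1, A = 1)
  rb <- feedback_rates(s, p, scenario("r(Q,A),b(A)"))
  expect_equal(rb[["r"]], 0.5)

  # inhibitor absent -> b at its maximum
  s0 <- lineage_state(Q = 5, A = 0)
  rb0 <- feedback_rates(s0, p, scenario("r(Q,A),b(A)"))
  expect_equal(rb0[["b"]], p$b0)

  # numerator vanishes with Q = 0 regardless of A
  pq <- unit_params(b0 = 0.8, beta = 0.01)
  for (A in c(0, 3, 100)) {
    s <- lineage_state(Q = 0, A = A)
    expect_equal(feedback_rates(s, pq, scenario("r(Q,Q+A),b(Q)"))[["r"]], 0)
  }

  # extended numerator keeps r positive at the empty state
  pko <- model_parameters(r0 = 1, K = 10, b0 = 0.6, beta = 0.01, r1 = 5)
  sko <- scenario("r*(Q,A),b(Q)")
  expect_equal(
    feedback_rates(lineage_state(0, 0), pko, sko)[["r"]], 5 / 10)
})

test_that("lineage right-hand side matches hand computation and its exact identity", {
  p <- unit_params()  # r0=1, K=1, b0=0.5, beta ~ 0, pA=pT=delta=1
  sc <- scenario("r(Q,A),b(A)")
  st <- lineage_state(Q = 1, A = 1, T = rep(0, 4), N = 0)
  d <- rhs_lineage(0, st, p, sc)
  expect_equal(unname(d), c(0.5, -0.5, 1, 0, 0, 0, 0), tolerance = 1e-9)

  # extinction state is an equilibrium
  expect_equal(unname(rhs_lineage(0, lineage_state(0, 0), p, sc)),
               rep(0, 7))

  # d(Q+A)/dt = (2b - 1) pA A holds exactly for random states and scenarios
  set.seed(41)
  pr <- model_parameters(r0 = 0.3, K = 500, b0 = 0.8, beta = 0.002)
  for (nm in list_scenarios(wild_type_only = TRUE)) {
    sc <- scenario(nm)
    for (i in 1:10) {
      st <- lineage_state(runif(1, 0, 3000), runif(1, 0, 2000),
                          runif(4, 0, 5000), runif(1, 0, 2e4))
      d <- rhs_lineage(0, st, pr, sc)
      b <- feedback_rates(st, pr, sc)[["b"]]
      expect_equal(d[["Q"]] + d[["A"]], (2 * b - 1) * pr$pA * st[["A"]],
                   tolerance = 1e-12)
    }
  }

  # with no active cells the TAP/NB chain receives no NSC input
  st <- lineage_state(Q = 100, A = 0)
  d <- rhs_lineage(0, st, p, sc)
  r <- feedback_rates(st, p, sc)[["r"]]
  expect_equal(d[["Q"]], -r * 100)
  expect_equal(d[["A"]], r * 100)
  expect_equal(unname(d[c("T0", "T1", "T2", "T3")]), rep(0, 4))

  # mismatched state length is a shape error
  expect_error(rhs_lineage(0, c(1, 2, 3), p, sc), "length")
})

test_that("chemotherapy right-hand side adds killing only on A and TAPs", {
  p <- unit_params()
  sc <- scenario("r(Q,A),b(A)")
  st <- lineage_state(Q = 1, A = 1, T = rep(0, 4), N = 0)
  expect_identical(rhs_tmz(0, st, p, sc, d = 0), rhs_lineage(0, st, p, sc))

  # quiescent-only state is untouched by the death rate
  stq <- lineage_state(Q = 50, A = 0)
  expect_identical(rhs_tmz(0, stq, p, sc, d = 2),
                   rhs_lineage(0, stq, p, sc))

  d1 <- rhs_tmz(0, st, p, sc, d = 1)
  expect_equal(d1[["A"]], -1.5)
  d0 <- rhs_lineage(0, st, p, sc)
  expect_equal(d1[c("Q", "T0", "T1", "T2", "T3", "N")],
               d0[c("Q", "T0", "T1", "T2", "T3", "N")])
  expect_error(rhs_tmz(0, st, p, sc, d = -1), "nonnegative")
})

test_that("simulation preserves equilibria, nonnegativity and the depletion bound", {
  p <- model_parameters(r0 = 0.2, K = 800, b0 = 0.75, beta = 0.002)
  sc <- scenario("r(Q,A),b(A)")
  eq <- steady_states(p, sc)[[2]]$state
  tr <- simulate_lineage(p, sc, eq, seq(0, 500, by = 50))
  for (cn in names(eq))
    expect_lt(max(abs(tr[[cn]] - eq[[cn]]) / eq[[cn]]), 1e-6)

  # nonnegativity from random nonnegative starts, all scenarios
  set.seed(99)
  for (nm in list_scenarios(wild_type_only = TRUE)) {
    st <- lineage_state(runif(1, 0, 3000), runif(1, 0, 1500),
                        runif(4, 0, 4000), runif(1, 0, 2e4))
    tr <- simulate_lineage(p, scenario(nm), st, seq(0, 700, by = 20))
    expect_gte(min(as.matrix(tr[, names(st)])), -1e-9)
  }

  # subcritical self-renewal: total NSC count never increases
  psub <- model_parameters(r0 = 0.2, K = 800, b0 = 0.4, beta = 0.002)
  for (nm in list_scenarios(wild_type_only = TRUE)) {
    tr <- simulate_lineage(psub, scenario(nm),
                           initial_state(psub, tap_total = 2000,
                                         nb_total = 8000),
                           seq(0, 700, by = 5))
    expect_lte(max(diff(tr$nsc_total)), 1e-6)
  }

  # supercritical: long-horizon trajectory converges to the positive
  # equilibrium found independently by the steady-state solver
  tr <- simulate_lineage(p, sc, initial_state(p, tap_total = 500,
                                              nb_total = 1000),
                         c(0, 5000))
  final <- unlist(tr[nrow(tr), names(eq)])
  expect_equal(unname(final), unname(eq), tolerance = 1e-5)

  expect_error(simulate_lineage(p, sc, eq, c(3, 2, 1)), "increasing")
})

test_that("piecewise TMZ simulation is continuous and reduces to the healthy model", {
  p <- default_parameters()
  sc <- wt_scenario()
  init <- initial_state(p, tap_total = 5000, nb_total = 23000)
  times <- seq(30, 300, by = 2)

  proto0 <- tmz_protocol(treatment_age = 60, d = 0, rho = 50, window = 3)
  tm <- simulate_tmz(proto0, p, sc, init, times)
  plain <- simulate_lineage(p, sc, init, sort(unique(c(times, 60, 63))))
  idx <- match(tm$time_days, plain$time_days)
  expect_equal(tm$nsc_total, plain$nsc_total[idx], tolerance = 1e-6)
  expect_equal(tm$nb_total, plain$nb_total[idx], tolerance = 1e-6)

  # state continuity at both switch times (left limit = next regime's IC)
  proto <- tmz_protocol(treatment_age = 60, d = 2, rho = 50, window = 3)
  fine <- sort(unique(c(times, 60 - 1e-6, 60, 63 - 1e-6, 63)))
  tm2 <- simulate_tmz(proto, p, sc, init, fine)
  for (tt in c(60, 63)) {
    left <- tm2[abs(tm2$time_days - (tt - 1e-6)) < 1e-9, ]
    at <- tm2[tm2$time_days == tt, ]
    expect_equal(unlist(left[1, names(init)]),
                 unlist(at[1, names(init)]), tolerance = 1e-5)
  }

  # strong killing: proliferating pool collapses below 5% within the window
  proto5 <- tmz_protocol(treatment_age = 60, d = 5, rho = 50, window = 3)
  tm5 <- simulate_tmz(proto5, p, sc, init, sort(unique(c(times, 63))))
  pre <- tm5$brdu_total[tm5$time_days == 60]
  post <- tm5$brdu_total[tm5$time_days == 63]
  expect_lt(post / pre, 0.05)

  # section scale is the whole-region pool divided by rho
  expect_equal(tm5$brdu_section, tm5$brdu_total / 50)
  expect_error(tmz_protocol(60, d = 1, rho = 50, window = -1), "window")
  expect_error(simulate_tmz(proto, p, sc, init, seq(400, 500, 10)),
               "treatment_age")
})

test_that("trajectory export writes the documented CSV layout", {
  p <- default_parameters()
  tr <- simulate_lineage(p, wt_scenario(),
                         initial_state(p, tap_total = 100), c(30, 50, 80))
  path <- tempfile(fileext = ".csv")
  export_trajectory(tr, path)
  back <- read.csv(path)
  expect_named(back, c("time_days", "Q", "A", paste0("T", 0:3), "N",
                       "nsc_total", "frac_active", "tap_total", "nb_total"))
  expect_equal(back$nsc_total, tr$nsc_total, tolerance = 1e-10)
  unlink(path)
})
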
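test_that("zero noise reproduces the trajectory exactly and seeds fix the draws", {
  sc <- wt_scenario()
  obs4 <- c("nsc_total", "frac_active", "tap_total", "nb_total")
  zero_vms <- stats::setNames(lapply(obs4, function(o) const_vm(0, o)),
                              obs4)
  cfg0 <- generator_config(sc, ages = c(30, 120, 400),
                           mice_per_age = 3, variance_models = zero_vms,
                           seed = 1)
  ds0 <- generate_dataset(cfg0)
  traj <- attr(ds0, "truth")$trajectory
  for (i in seq_along(cfg0$ages))
    for (o in obs4)
      expect_equal(
        ds0$value[ds0$age_days == cfg0$ages[i] & ds0$observable == o],
        rep(traj[[o]][i], 3))

  cfg <- generator_config(sc, ages = c(30, 120, 400), mice_per_age = 4,
                          seed = 33)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_dataset(generate_dataset(cfg), f1)
  write_dataset(generate_dataset(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical replay
  unlink(c(f1, f2))
})

test_that("per-age sample means track the trajectory at high replication", {
  sc <- wt_scenario()
  cfg <- generator_config(sc, ages = c(30, 150, 500), mice_per_age = 200,
                          seed = 10)
  ds <- generate_dataset(cfg)
  truth <- attr(ds, "truth")
  for (i in seq_along(cfg$ages)) {
    for (o in c("nsc_total", "tap_total", "nb_total")) {
      v <- ds$value[ds$age_days == cfg$ages[i] & ds$observable == o]
      target <- truth$trajectory[[o]][i]
      se <- sd(v) / sqrt(length(v))
      # truncation at zero biases means by < se here; allow 3.5 se
      expect_lt(abs(mean(v) - target), 3.5 * se + 0.005 * target)
    }
  }
})

test_that("chemotherapy datasets reflect killing, scaling and recovery", {
  sc <- wt_scenario()
  wt <- default_parameters()

  # no killing, identical post-parameters: post-treatment section means
  # equal the unperturbed trajectory divided by rho, up to noise
  proto0 <- tmz_protocol(treatment_age = 60, d = 0, rho = 40, window = 3)
  cfg0 <- generator_config(sc, setting = "TMZ_young", protocol = proto0,
                           mice_per_age = 150, seed = 4)
  ds0 <- generate_tmz_dataset(cfg0)
  plain <- simulate_lineage(wt, sc,
                            initial_state(wt, tap_total = 5000,
                                          nb_total = 23000),
                            c(30, 56, 60, 61, 69, 95))
  for (a in c(61, 69, 95)) {
    v <- ds0$value[ds0$setting == "TMZ_young" & ds0$age_days == a]
    target <- (plain$A + plain$tap_total)[plain$time_days == a] / 40
    expect_lt(abs(mean(v) - target) / target, 0.1)
  }

  # rho = 1 puts sections on the whole-region scale
  proto1 <- tmz_protocol(treatment_age = 60, d = 0, rho = 1, window = 3)
  cfg1 <- generator_config(sc, setting = "TMZ_young", protocol = proto1,
                           mice_per_age = 50, seed = 5)
  ds1 <- generate_tmz_dataset(cfg1)
  sal <- ds1$value[ds1$setting == "saline_young"]
  whole <- (plain$A + plain$tap_total)[plain$time_days == 56]
  expect_lt(abs(mean(sal) - whole) / whole, 0.15)

  # strong killing: day-1 mean far below day-35 mean (recovery shape)
  proto <- tmz_protocol(treatment_age = 60, d = 3, rho = 40, window = 3)
  cfg <- generator_config(sc, setting = "TMZ_young", protocol = proto,
                          mice_per_age = 20, seed = 6)
  ds <- generate_tmz_dataset(cfg)
  m1 <- mean(ds$value[ds$age_days == 61])
  m35 <- mean(ds$value[ds$age_days == 95])
  expect_lt(m1, 0.5 * m35)

  expect_error(generate_tmz_dataset(generator_config(sc, setting = "WT")),
               "tmz_protocol")
})
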
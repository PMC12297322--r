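#' Configuration for the synthetic-dataset generator
#'
#' Describes a simulated mouse cohort: the generating scenario and "true"
#' parameters, the observation ages (default: 10 ages log-spaced over
#' 30--700 days, matching the span of the mouse data), the number of mice
#' per age, the per-observable noise models and, for chemotherapy settings,
#' the treatment protocol.
#'
#' When `variance_models` is `NULL` they are derived once from the true
#' trajectory so that the cross-mouse coefficient of variation is about 25%
#' at the first age and decays (rate `0.008`/day) towards about 10% — the
#' visual scatter of published cohorts. Noise is truncated-normal: counts
#' at zero, the active fraction within `[0, 1]`, so no probability mass
#' piles up at the bounds.
#'
#' @param scenario a [scenario()] (the generating truth).
#' @param true_params the generating [model_parameters()].
#' @param ages observation ages (days), increasing.
#' @param mice_per_age mice sampled at each age (>= 1).
#' @param setting dataset label (`"WT"` or `"KO"`).
#' @param variance_models optional named list of `"variance_model"`s.
#' @param protocol a [tmz_protocol()] for TMZ generation.
#' @param f0,tap0,nb0 initial active fraction and TAP/NB totals of the true
#'   trajectory.
#' @param seed RNG seed; the emitted dataset is deterministic given it.
#' @return Object of class `"generator_config"`.
#' @export
generator_config <- function(scenario, true_params = default_parameters(),
                             ages = round(exp(seq(log(30), log(700),
                                                  length.out = 10))),
                             mice_per_age = 4, setting = "WT",
                             variance_models = NULL, protocol = NULL,
                             f0 = 0.3, tap0 = 5000, nb0 = 23000, seed = 1) {
  stopifnot("ages must be increasing" = all(diff(ages) > 0),
            "mice_per_age must be >= 1" = mice_per_age >= 1)
  structure(list(scenario = scenario, true_params = true_params,
                 ages = ages, mice_per_age = mice_per_age,
                 setting = setting, variance_models = variance_models,
                 protocol = protocol, f0 = f0, tap0 = tap0, nb0 = nb0,
                 seed = seed),
            class = "generator_config")
}

## Default noise models anchored to the true trajectory: sd(t) interpolates
## from 25% of the first-age value to 10% of the last-age value.
.auto_variance_models <- function(traj, t0, decay = 0.008) {
  obs <- c("nsc_total", "frac_active", "tap_total", "nb_total")
  out <- lapply(obs, function(o) {
    y1 <- traj[[o]][1]
    y2 <- traj[[o]][nrow(traj)]
    d0 <- 0.10 * y2
    d1 <- max(0.25 * y1 - d0, 0)
    structure(list(d0 = d0, d1 = d1, d3 = decay, t0 = t0, observable = o),
              class = "variance_model")
  })
  stats::setNames(out, obs)
}

#' Generate a synthetic longitudinal dataset
#'
#' Simulates the true trajectory, then draws per-mouse observations
#' `value ~ Normal(trajectory, sigma_obs(age))`, truncated to valid ranges,
#' independently across mice and ages. The generating truth (parameters,
#' scenario, seed, variance models) is attached as the `"truth"` attribute
#' so downstream recovery checks are self-contained.
#'
#' @param config a [generator_config()].
#' @return A validated dataset data frame with attribute `truth`.
#' @examples
#' cfg <- generator_config(scenario("r(Q,A),b(Q)"), mice_per_age = 2,
#'                         ages = c(30, 120, 360, 700), seed = 42)
#' d <- generate_dataset(cfg)
#' head(d)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  p <- config$true_params
  init <- initial_state(p, f0 = config$f0, tap_total = config$tap0,
                        nb_total = config$nb0)
  traj <- simulate_lineage(p, config$scenario, init, config$ages)
  vms <- config$variance_models %||%
    .auto_variance_models(traj, config$ages[1])
  if (min(traj$nsc_total) < 1)
    warning("trajectory falls below one NSC before the last age; ",
            "data emitted anyway")

  set.seed(config$seed)
  obs <- c("nsc_total", "frac_active", "tap_total", "nb_total")
  rows <- list()
  for (ia in seq_along(config$ages)) {
    age <- config$ages[ia]
    for (o in obs) {
      mu <- traj[[o]][ia]
      sd <- predict_sd(vms[[o]], age)
      upper <- if (o == "frac_active") 1 else Inf
      vals <- rtnorm(config$mice_per_age, mu, sd, 0, upper)
      rows[[length(rows) + 1]] <- data.frame(
        setting = config$setting,
        mouse_id = sprintf("%s_a%02d_m%02d", config$setting, ia,
                           seq_len(config$mice_per_age)),
        age_days = age, observable = o, value = vals)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_dataset(out)
  attr(out, "truth") <- list(params = unclass(p),
                             scenario = config$scenario$name,
                             seed = config$seed, variance_models = vms,
                             trajectory = traj)
  out
}

#' Generate a synthetic TMZ (chemotherapy) dataset
#'
#' Emits section-scale BrdU+ counts: saline baselines at the treatment age
#' (from the unperturbed trajectory) and post-treatment observations at the
#' given offsets (default 1, 9 and 35 days after treatment, the recovery
#' time points recorded experimentally). Section values are the
#' whole-region proliferating pool divided by the protocol's `rho`, plus
#' truncated Gaussian noise with a coefficient of variation `cv`.
#'
#' @param config a [generator_config()] whose `protocol` is set and whose
#'   `setting` is `"TMZ_young"` or `"TMZ_old"`.
#' @param offsets observation times after treatment (days).
#' @param saline_lead days before treatment at which the saline baseline is
#'   recorded.
#' @param cv observation noise, as a fraction of the section-scale mean.
#' @return A validated dataset (settings `TMZ_*` and the matching
#'   `saline_*`) with attribute `truth`.
#' @export
generate_tmz_dataset <- function(config, offsets = c(1, 9, 35),
                                 saline_lead = 4, cv = 0.2) {
  stopifnot(inherits(config, "generator_config"),
            "config$protocol must be a tmz_protocol" =
              inherits(config$protocol, "tmz_protocol"),
            config$setting %in% c("TMZ_young", "TMZ_old"))
  p <- config$true_params
  proto <- config$protocol
  saline_setting <- sub("TMZ", "saline", config$setting)
  init <- initial_state(p, f0 = config$f0, tap_total = config$tap0,
                        nb_total = config$nb0)
  attr(init, "age0") <- min(config$ages)
  saline_age <- max(proto$treatment_age - saline_lead, min(config$ages))
  t_obs <- proto$treatment_age + offsets
  times <- sort(unique(c(min(config$ages), saline_age,
                         proto$treatment_age, t_obs)))
  traj <- simulate_tmz(proto, p, config$scenario, init, times)

  set.seed(config$seed)
  emit <- function(setting, age, mu_section) {
    sd <- cv * max(mu_section, 1e-8)
    vals <- rtnorm(config$mice_per_age, mu_section, sd, 0, Inf)
    data.frame(setting = setting,
               mouse_id = sprintf("%s_t%04d_m%02d", setting, round(age),
                                  seq_len(config$mice_per_age)),
               age_days = age, observable = "brdu_section", value = vals)
  }
  rows <- list(emit(saline_setting, saline_age,
                    traj$brdu_section[traj$time_days == saline_age]))
  for (tt in t_obs)
    rows[[length(rows) + 1]] <-
      emit(config$setting, tt, traj$brdu_section[traj$time_days == tt])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_dataset(out)
  attr(out, "truth") <- list(params = unclass(p),
                             scenario = config$scenario$name,
                             protocol = unclass(proto), seed = config$seed,
                             trajectory = traj)
  out
}
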
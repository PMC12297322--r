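#' Run one pipeline stage and write its artifacts
#'
#' Ties the stages together into a reproducible run: `generate` emits a
#' synthetic dataset CSV, `fit` a multistart WLS fit (JSON), `select` a
#' model-selection table (CSV + JSON), `simulate` a trajectory CSV, `tmz` a
#' perturbed trajectory CSV and `mcmc` a posterior chain (CSV + JSON
#' diagnostics). Every run writes a `manifest.json` recording inputs,
#' seeds, package version and wall-clock time, so any stochastic artifact
#' can be replayed from its manifest.
#'
#' @param config a named list (or path to a JSON file) with at least
#'   `command` and `out_dir`; further fields depend on the command:
#'   \describe{
#'     \item{generate}{`scenario`, optional `params` (named list), `ages`,
#'       `mice_per_age`, `setting`, `seed`.}
#'     \item{fit}{`data` (dataset CSV path), `scenario`, `setting`,
#'       `n_starts`, `seed`.}
#'     \item{select}{`fits` (character vector of fit JSON paths) or
#'       `fit_objects` (list of fits).}
#'     \item{simulate}{`scenario`, optional `params`, `t_start`, `t_end`.}
#'     \item{tmz}{as simulate plus `treatment_age`, `d`, `rho`, `window`.}
#'     \item{mcmc}{`data`, `scenario`, `setting`, `n_samples`, `seed`.}
#'   }
#' @return Invisibly, a list of artifact paths (also recorded in the
#'   manifest). Errors on schema violations.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  if (is.null(config$command))
    stop("config must name a `command` ",
         "(simulate | fit | select | mcmc | generate | tmz)")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  seed <- config$seed %||% 1

  get_params <- function() {
    if (is.null(config$params)) default_parameters()
    else update_params(default_parameters(), config$params)
  }
  get_scenario <- function() scenario(config$scenario %||%
                                        stop("config needs `scenario`"))

  artifacts <- switch(
    config$command,
    generate = {
      cfg <- generator_config(
        scenario = get_scenario(), true_params = get_params(),
        ages = config$ages %||% round(exp(seq(log(30), log(700),
                                              length.out = 10))),
        mice_per_age = config$mice_per_age %||% 4,
        setting = config$setting %||% "WT", seed = seed)
      ds <- generate_dataset(cfg)
      path <- file.path(out_dir, "dataset.csv")
      write_dataset(ds, path)
      truth_path <- file.path(out_dir, "dataset_truth.json")
      tr <- attr(ds, "truth")
      jsonlite::write_json(list(scenario = tr$scenario, params = tr$params,
                                seed = tr$seed),
                           truth_path, auto_unbox = TRUE, digits = NA)
      c(dataset = path, truth = truth_path)
    },
    fit = {
      ds <- read_dataset(config$data %||% stop("config needs `data`"))
      fit <- fit_multistart(ds, get_scenario(),
                            setting = config$setting %||% "WT",
                            base_params = get_params(),
                            n_starts = config$n_starts %||% 500,
                            seed = seed)
      path <- file.path(out_dir, "fit.json")
      write_fit_json(fit, path)
      rds_free <- file.path(out_dir, "fit_estimates.csv")
      utils::write.csv(data.frame(parameter = names(fit$par),
                                  estimate = unname(fit$par)),
                       rds_free, row.names = FALSE, quote = FALSE)
      c(fit = path, estimates = rds_free)
    },
    select = {
      fits <- config$fit_objects %||%
        stop("select expects `fit_objects` (a list of lineage_fit objects)")
      tab <- build_selection_table(fits)
      write_selection_table(tab, file.path(out_dir, "selection.csv"),
                            file.path(out_dir, "selection.json"))
      c(selection_csv = file.path(out_dir, "selection.csv"),
        selection_json = file.path(out_dir, "selection.json"))
    },
    simulate = {
      p <- get_params()
      times <- seq(config$t_start %||% 30, config$t_end %||% 700,
                   length.out = config$n_times %||% 200)
      tr <- simulate_lineage(p, get_scenario(),
                             initial_state(p, tap_total = 2000,
                                           nb_total = 9000), times)
      path <- file.path(out_dir, "trajectory.csv")
      export_trajectory(tr, path)
      c(trajectory = path)
    },
    tmz = {
      p <- get_params()
      proto <- tmz_protocol(
        treatment_age = config$treatment_age %||% 60,
        d = config$d %||% 1, rho = config$rho %||% 50,
        window = config$window %||% 3)
      times <- seq(config$t_start %||% 30, config$t_end %||% 700,
                   length.out = config$n_times %||% 200)
      tr <- simulate_tmz(proto, p, get_scenario(),
                         initial_state(p, tap_total = 2000,
                                       nb_total = 9000), times)
      path <- file.path(out_dir, "tmz_trajectory.csv")
      export_trajectory(tr, path)
      c(tmz_trajectory = path)
    },
    mcmc = {
      ds <- read_dataset(config$data %||% stop("config needs `data`"))
      sc <- get_scenario()
      setting <- config$setting %||% "WT"
      base <- get_params()
      free <- free_params_for_setting(setting)
      free <- intersect(free, c("r0", "r1", "K", "b0", "beta", "pT"))
      init <- unlist(unclass(base)[free])
      bounds <- default_bounds()[free]
      target <- function(theta) {
        names(theta) <- free
        p <- update_params(base, as.list(theta))
        -neg_log_likelihood(p, sc, ds, setting,
                            n_ic_reps = config$n_ic_reps %||% 3)$value
      }
      chain <- adaptive_metropolis(target, init,
                                   n_samples = config$n_samples %||% 5000,
                                   bounds = bounds, seed = seed)
      write_chain(chain, file.path(out_dir, "chain.csv"),
                  file.path(out_dir, "chain_diagnostics.json"))
      c(chain = file.path(out_dir, "chain.csv"),
        diagnostics = file.path(out_dir, "chain_diagnostics.json"))
    },
    stop("unknown command '", config$command, "'")
  )

  manifest <- list(
    command = config$command,
    inputs = config[setdiff(names(config), c("fit_objects"))],
    seed = seed,
    artifacts = as.list(artifacts),
    package_version = as.character(utils::packageVersion("nscfeedback")),
    wall_clock_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(artifacts, manifest = manifest_path))
}
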
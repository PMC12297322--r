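.observables <- c("nsc_total", "frac_active", "tap_total", "nb_total",
                  "brdu_section")
.settings <- c("WT", "KO", "TMZ_young", "TMZ_old",
               "saline_young", "saline_old")

#' Validate a longitudinal dataset
#'
#' Datasets are long-format data frames with one row per mouse, age and
#' observable: columns `setting` (one of `WT`, `KO`, `TMZ_young`, `TMZ_old`,
#' `saline_young`, `saline_old`), `mouse_id`, `age_days`, `observable`
#' (`nsc_total`, `frac_active`, `tap_total`, `nb_total` or `brdu_section`)
#' and `value`.
#'
#' @param dataset a data frame.
#' @return The dataset, invisibly, or an error.
#' @export
validate_dataset <- function(dataset) {
  need <- c("setting", "mouse_id", "age_days", "observable", "value")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  bad_set <- setdiff(unique(dataset$setting), .settings)
  if (length(bad_set))
    stop("unknown setting(s): ", paste(bad_set, collapse = ", "))
  bad_obs <- setdiff(unique(dataset$observable), .observables)
  if (length(bad_obs))
    stop("unknown observable(s): ", paste(bad_obs, collapse = ", "))
  if (any(dataset$value < 0)) stop("values must be nonnegative")
  if (any(dataset$age_days <= 0)) stop("ages must be positive")
  fr <- dataset$value[dataset$observable == "frac_active"]
  if (any(fr > 1)) stop("frac_active values must lie in [0, 1]")
  invisible(dataset)
}

#' Read / write a dataset CSV
#'
#' The on-disk dialect is a plain UTF-8 CSV with header
#' `setting,mouse_id,age_days,observable,value` and `.` as decimal mark.
#'
#' @param path file path.
#' @return `read_dataset()` returns the validated data frame.
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_dataset(df)
  df
}

#' @rdname read_dataset
#' @param dataset a validated dataset data frame.
#' @export
write_dataset <- function(dataset, path) {
  validate_dataset(dataset)
  utils::write.csv(dataset, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Per-(age, observable) summary used for weighting and likelihoods.
dataset_groups <- function(dataset) {
  agg <- stats::aggregate(value ~ age_days + observable, data = dataset,
                          FUN = function(v) c(mean = mean(v),
                                              var = stats::var(v),
                                              n = length(v)))
  out <- data.frame(age_days = agg$age_days, observable = agg$observable,
                    mean = agg$value[, "mean"], var = agg$value[, "var"],
                    n_mice = agg$value[, "n"])
  out[order(out$observable, out$age_days), , drop = FALSE]
}

#' Initial conditions implied by the first observation age
#'
#' The simulation's time origin is anchored at the first observation age.
#' The total NSC count at that age is the fixed `NSC0`; its split between
#' quiescent and active cells uses the mean observed active fraction at the
#' first age (falling back to `f0_fallback` when absent); TAP and
#' neuroblast totals come from the first-age data means, with the TAP total
#' split equally over compartments.
#'
#' @param dataset a dataset restricted to one setting.
#' @param params a [model_parameters()] object.
#' @param f0_fallback active fraction used when no first-age fraction data.
#' @return A [lineage_state()] vector with attribute `age0`.
#' @export
initial_conditions_from_data <- function(dataset, params, f0_fallback = 0.3) {
  validate_dataset(dataset)
  age0 <- min(dataset$age_days)
  at0 <- dataset[dataset$age_days == age0, , drop = FALSE]
  mean_of <- function(obs, fallback) {
    v <- at0$value[at0$observable == obs]
    if (length(v)) mean(v) else fallback
  }
  f0 <- mean_of("frac_active", f0_fallback)
  st <- initial_state(params, f0 = f0,
                      tap_total = mean_of("tap_total", 0),
                      nb_total = mean_of("nb_total", 0))
  attr(st, "age0") <- age0
  st
}
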
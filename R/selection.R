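#' Akaike information criterion for weighted least squares
#'
#' For a weighted least-squares fit with minimized cost `E`, data size `n`
#' and `k` fitted parameters:
#' \deqn{AIC = n \ln(E/n) + 2k, \qquad AICc = AIC + \frac{2k(k+1)}{n-k-1}.}
#' The small-sample correction requires `n > k + 1`.
#'
#' @param E minimized cost (> 0).
#' @param n number of residuals.
#' @param k number of fitted parameters.
#' @return Named vector `c(AIC, AICc)`.
#' @examples
#' aicc(E = 10, n = 10, k = 2)  # AIC = 4, AICc = 4 + 12/7
#' @export
aicc <- function(E, n, k) {
  stopifnot("E must be positive" = E > 0, "n and k must be >= 0" = n > 0 &&
              k >= 0)
  if (n <= k + 1)
    stop("small-sample correction undefined: need n > k + 1 (n = ", n,
         ", k = ", k, ")")
  AIC <- n * log(E / n) + 2 * k
  c(AIC = AIC, AICc = AIC + 2 * k * (k + 1) / (n - k - 1))
}

#' Akaike weights
#'
#' Normalized relative likelihoods \eqn{w_i = \exp(-\Delta_i/2) /
#' \sum_j \exp(-\Delta_j/2)} with \eqn{\Delta_i = AICc_i - \min_j AICc_j};
#' invariant under adding a constant to all scores.
#'
#' @param scores vector of AICc (or AIC) values, all finite.
#' @return Vector of weights summing to 1.
#' @examples
#' akaike_weights(c(0, 2))  # ~ (0.731, 0.269)
#' @export
akaike_weights <- function(scores) {
  if (!length(scores)) stop("need at least one score")
  stopifnot("scores must be finite" = all(is.finite(scores)))
  d <- scores - min(scores)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Model-selection table across scenarios
#'
#' Ranks a set of fits by AICc and attaches the differences to the best
#' model and the Akaike weights. With `pooling = "per_setting"` each setting
#' is ranked on its own; with `pooling = "overall"` scenarios are compared
#' on their total cost, summing `E` and `n` over settings and counting each
#' free-parameter symbol once across the pooled fits (an approximation,
#' flagged in the `pooled` attribute).
#'
#' @param fits list of `"lineage_fit"` objects (same dataset per setting).
#' @param pooling `"per_setting"` or `"overall"`.
#' @return A data frame with columns `scenario`, `setting`, `E`, `n`, `k`,
#'   `AIC`, `AICc`, `delta_AICc`, `weight`, sorted by AICc within setting.
#' @export
build_selection_table <- function(fits, pooling = c("per_setting",
                                                    "overall")) {
  pooling <- match.arg(pooling)
  stopifnot(all(vapply(fits, inherits, logical(1), "lineage_fit")))

  if (pooling == "overall") {
    by_scenario <- split(fits, vapply(fits, `[[`, character(1), "scenario"))
    rows <- lapply(by_scenario, function(fs) {
      k_union <- length(unique(unlist(lapply(fs, function(f)
        names(f$par)))))
      data.frame(scenario = fs[[1]]$scenario, setting = "overall",
                 E = sum(vapply(fs, `[[`, numeric(1), "E")),
                 n = sum(vapply(fs, `[[`, numeric(1), "n")),
                 k = k_union)
    })
    tab <- do.call(rbind, rows)
    setting_groups <- list(overall = tab)
  } else {
    tab <- data.frame(
      scenario = vapply(fits, `[[`, character(1), "scenario"),
      setting = vapply(fits, `[[`, character(1), "setting"),
      E = vapply(fits, `[[`, numeric(1), "E"),
      n = vapply(fits, `[[`, numeric(1), "n"),
      k = vapply(fits, `[[`, numeric(1), "k"))
    for (s in unique(tab$setting)) {
      ns <- unique(tab$n[tab$setting == s])
      if (length(ns) > 1)
        stop("fits within setting ", s,
             " have different data sizes; mixed datasets?")
    }
    setting_groups <- split(tab, tab$setting)
  }

  out <- lapply(setting_groups, function(g) {
    sc <- t(mapply(aicc, g$E, g$n, g$k))
    g$AIC <- sc[, "AIC"]
    g$AICc <- sc[, "AICc"]
    g$delta_AICc <- g$AICc - min(g$AICc)
    g$weight <- akaike_weights(g$AICc)
    g[order(g$AICc), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pooled") <- pooling == "overall"
  res
}

#' Write a selection table to CSV and JSON
#'
#' @param table a selection table from [build_selection_table()].
#' @param path_csv,path_json output paths (either may be `NULL`).
#' @export
write_selection_table <- function(table, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv))  # scenario names contain commas: keep quoting
    utils::write.csv(table, path_csv, row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(table, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(table)
}
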
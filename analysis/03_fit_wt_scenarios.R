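#!/usr/bin/env Rscript

# Stage 3 — which populations regulate the wild-type lineage? Fits all
# five feedback scenarios to the wild-type cohort by multistart weighted
# least squares, compares them with AICc / Akaike weights, and reports the
# linearized uncertainty of the winning fit. Run stage 2 first.

suppressPackageStartupMessages(library(nscfeedback))
out_dir <- "results/analysis"
ds <- read_dataset(file.path(out_dir, "wt_dataset.csv"))
truth <- jsonlite::read_json(file.path(out_dir, "wt_truth.json"),
                             simplifyVector = TRUE)

fits <- lapply(list_scenarios(wild_type_only = TRUE), function(nm) {
  fit <- fit_multistart(ds, scenario(nm), "WT", n_starts = 200,
                        n_refine = 16, seed = 301)
  write_fit_json(fit, file.path(out_dir, paste0(
    "fit_wt_", gsub("[^A-Za-z0-9]+", "_", nm), ".json")))
  fit
})

tab <- build_selection_table(fits)
write_selection_table(tab, file.path(out_dir, "wt_selection.csv"),
                      file.path(out_dir, "wt_selection.json"))
print(tab[, c("scenario", "E", "AICc", "delta_AICc", "weight")],
      row.names = FALSE)

best <- fits[[which(vapply(fits, `[[`, character(1), "scenario") ==
                      tab$scenario[1])]]
cat(sprintf("\nbest-scoring scenario: %s (Akaike weight %.1f%%)\n",
            best$scenario, 100 * tab$weight[1]))
cat(sprintf("generating scenario %s ranked %d of %d\n", truth$scenario,
            which(tab$scenario == truth$scenario), nrow(tab)))

flat <- character(0)
withCallingHandlers(
  cv <- linearized_covariance(best),
  warning = function(w) {
    flat <<- sub(".*involve: ", "", conditionMessage(w))
    invokeRestart("muffleWarning")
  })
cat("\nestimates +/- linearized SD (correlation with b0):\n")
for (nm in names(best$par))
  cat(sprintf("  %-5s %10.4g +/- %-10.3g corr(b0, .) = %+.2f\n",
              nm, best$par[[nm]], cv$std[[nm]],
              cv$correlation["b0", nm]))
if (length(flat) && nzchar(flat))
  cat("\nThe residual Jacobian is numerically rank deficient along:", flat,
      "\n— that direction (the activation half-saturation, trading off",
      "\nagainst r0) is practically unidentifiable from population counts;",
      "\nits linearized SD is not meaningful and the Bayesian stage maps",
      "\nthe ridge instead. b0 and beta are strongly correlated, as the",
      "\nform of the self-renewal feedback suggests.\n")
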
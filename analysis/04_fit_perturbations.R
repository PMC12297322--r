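#!/usr/bin/env Rscript

# Stage 4 — perturbation experiments. Fits the chemotherapy cohorts
# (young and old) with the wild-type parameters held fixed except the
# treatment-sensitive set, and the receptor-knockout cohort with the
# extended activation numerator. Run stage 2 first.

suppressPackageStartupMessages(library(nscfeedback))
out_dir <- "results/analysis"
sc <- scenario("r(Q,A),b(Q)")
wt_params <- default_parameters()

cat("== chemotherapy (TMZ) ==\n")
for (setting in c("TMZ_young", "TMZ_old")) {
  ds <- read_dataset(file.path(out_dir, paste0(tolower(setting),
                                               "_dataset.csv")))
  truth <- jsonlite::read_json(file.path(out_dir, paste0(tolower(setting),
                                                         "_truth.json")),
                               simplifyVector = TRUE)
  base_proto <- tmz_protocol(truth$protocol$treatment_age, d = 1, rho = 1,
                             window = truth$protocol$window)
  fit <- fit_multistart(ds, sc, setting, base_params = wt_params,
                        base_protocol = base_proto, n_starts = 120,
                        n_refine = 10, seed = 401)
  write_fit_json(fit, file.path(out_dir, paste0("fit_", tolower(setting),
                                                ".json")))
  cat(sprintf("%s: pT = %.3f (wild type %.2f, true %.3f) | d = %.2f | rho = %.1f\n",
              setting, fit$par[["pT"]], wt_params$pT,
              truth$post_params$pT, fit$par[["d"]], fit$par[["rho"]]))
  if ("r0" %in% names(fit$par))
    cat(sprintf("          r0 = %.4f (wild type %.2f): deeper quiescence\n",
                fit$par[["r0"]], wt_params$r0))
}
cat("Treatment slows TAP cycling (fitted pT well below the wild-type\n")
cat("value): the drug removes fast-cycling progenitors and selects slow\n")
cat("ones; in old mice activation is additionally suppressed.\n\n")

cat("== interferon-receptor knockout ==\n")
ds_ko <- read_dataset(file.path(out_dir, "ko_dataset.csv"))
truth_ko <- jsonlite::read_json(file.path(out_dir, "ko_truth.json"),
                                simplifyVector = TRUE)
fit_ko <- fit_multistart(ds_ko, scenario("r*(Q,A),b(Q)"), "KO",
                         n_starts = 200, n_refine = 16, seed = 402)
write_fit_json(fit_ko, file.path(out_dir, "fit_ko.json"))
for (nm in names(fit_ko$par))
  cat(sprintf("  %-5s est %10.4g   true %10.4g\n", nm, fit_ko$par[[nm]],
              truth_ko$params[[nm]]))
cat("The fitted TAP division rate sits above the wild-type 0.81/day\n")
cat("(shorter knockout cell cycle). The activation constants r1, r0 and\n")
cat("K trade off along a ridge — a point estimate pins only the\n")
cat("effective activation rate, not the split between basal and\n")
cat("lineage-driven production; the posterior in stage 5 maps that\n")
cat("ridge explicitly.\n")
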
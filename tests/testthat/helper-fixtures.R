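# Shared fixtures: small parameter sets, the closed-form equilibrium oracle
# for the scenario in which active NSCs inhibit self-renewal, and compact
# dataset builders. Everything is generated in code at test time.

unit_params <- function(b0 = 0.5, beta = 1e-12, r0 = 1, K = 1) {
  model_parameters(r0 = r0, K = K, b0 = b0, beta = beta,
                   pA = 1, pT = 1, delta = 1)
}

# Closed form for the positive equilibrium of r(Q,A), b(A):
# Abar = (2 b0 - 1)/beta, Qbar = sqrt((pA/r0) Abar (K + Abar)), then the
# linear cascade at b = 1/2: T0 = pA Abar / pT, Ti = 2 T(i-1),
# N = 2^(n+1) pA Abar / delta. Derived independently of the package's
# Newton solver.
closed_form_bA <- function(p) {
  Abar <- (2 * p$b0 - 1) / p$beta
  Qbar <- sqrt((p$pA / p$r0) * Abar * (p$K + Abar))
  T0 <- p$pA * Abar / p$pT
  c(Q = Qbar, A = Abar,
    stats::setNames(T0 * 2^(0:p$n), paste0("T", 0:p$n)),
    N = 2^(p$n + 1) * p$pA * Abar / p$delta)
}

# constant-sd variance model (sigma supplied, no decay)
const_vm <- function(sd, observable, t0 = 0) {
  structure(list(d0 = sd, d1 = 0, d3 = 0, t0 = t0, observable = observable),
            class = "variance_model")
}

# long-format dataset from explicit (age, observable, values) triples
make_dataset <- function(rows, setting = "WT") {
  do.call(rbind, lapply(rows, function(r)
    data.frame(setting = setting,
               mouse_id = paste0("m", seq_along(r$values)),
               age_days = r$age, observable = r$observable,
               value = r$values)))
}

wt_scenario <- function() scenario("r(Q,A),b(Q)")

log_spaced_ages <- function(n, lo = 30, hi = 700)
  round(exp(seq(log(lo), log(hi), length.out = n)))
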
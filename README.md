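# nscfeedback

Feedback-regulated models of the adult neural stem cell (NSC) lineage in
the mouse ventricular–subventricular zone, for systems biologists asking
*which cell populations control stem-cell activation and self-renewal*
during ageing. The package provides the nonlinear compartmental model,
its steady-state/bifurcation analysis, weighted least-squares multistart
fitting, AICc model selection, adaptive Metropolis posterior sampling,
in silico chemotherapy (temozolomide) and interferon-receptor knockout
experiments, and a generator of synthetic per-mouse longitudinal
cohorts so the whole inference pipeline is testable without downloads.

## The model

Quiescent NSCs `Q` activate at rate `r` into cycling NSCs `A`, which
divide at rate `p_A`, self-renewing with probability `b` or producing
transient amplifying progenitors (TAPs) `T_0..T_3` that amplify at rate
`p_T` and feed neuroblasts `N` (exit rate `delta`):

    dQ/dt  = -rQ + 2 b pA A
    dA/dt  =  rQ - pA A
    dT0/dt = 2(1-b) pA A - pT T0
    dTi/dt = 2 pT T(i-1) - pT Ti        (i = 1..3)
    dN/dt  = 2 pT T3 - delta N

Regulation enters through Hill-type feedbacks on the two key rates,

    r = (r1 + r0 c1) / (K + c2),      b = b0 / (1 + beta c3),

where a *scenario* picks the populations `c1, c2, c3` (e.g.
`"r(Q,A),b(Q)"`: quiescent NSCs promote activation, active NSCs inhibit
it, quiescent NSCs inhibit self-renewal). Since
`d(Q+A)/dt = (2b - 1) pA A`, the maximal self-renewal fraction `b0`
carries a bifurcation at 1/2: below it the lineage dies out, above it a
stable positive steady state exists at which the realized `b` is
exactly 1/2.

## Worked example

```r
library(nscfeedback)

p  <- default_parameters()          # r0 0.2, K 1000, b0 0.52, beta 7.3e-5
sc <- scenario("r(Q,A),b(Q)")
init <- initial_state(p, f0 = 0.3, tap_total = 5000, nb_total = 23000)
simulate_lineage(p, sc, init, times = c(30, 120, 250, 450, 700))
#>   time_days nsc_total frac_active tap_total  nb_total
#> 1        30  1900.000       0.300  5000.000 23000.000
#> 2       120  1073.595       0.144  2859.998 13528.305
#> 3       250   812.285       0.121  1761.037  8128.491
#> 4       450   690.264       0.108  1319.500  6033.284
#> 5       700   639.734       0.102  1151.493  5246.949
```

The cohort loses two thirds of its stem cells over the lifespan while the
active fraction relaxes from 0.3 to 0.1 — because `b0 = 0.52 > 1/2` the
decline saturates at a positive equilibrium rather than running to
extinction:

```r
steady_states(p, sc)[[2]]
#> positive steady state (stable), residual 4.23e-15
#>        Q        A       T0       T1       T2       T3        N
#>  547.945   59.651   69.961  139.922  279.844  559.689 4772.081
```

Fitting a synthetic cohort (8 ages, 4 mice/age) recovers the
self-renewal feedback and ranks the generating wiring first:

```r
ds  <- generate_dataset(generator_config(sc,
         ages = round(exp(seq(log(30), log(700), length.out = 8))),
         seed = 1))
fit <- fit_multistart(ds, sc, "WT", n_starts = 100, n_refine = 10,
                      seed = 42)
fit
#> WLS fit: scenario r(Q,A),b(Q), setting WT
#>   E = 165.686 over n = 128 residuals, k = 4 free parameters
#>   estimates:
#>     r0    = 0.0667132
#>     K     = 253.731
#>     b0    = 0.514705
#>     beta  = 5.99853e-05
```

`b0` and `beta` land close to the generating values (0.52, 7.3e-5);
`r0` and `K` sit elsewhere on their shared ridge — only their ratio is
identified from population counts, which the posterior analysis
(`adaptive_metropolis()`) makes explicit.

## The analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/analysis/`:

1. `01_simulate_scenarios.R` — scenario dynamics, equilibria, the
   numerical bifurcation threshold.
2. `02_generate_data.R` — wild-type, knockout and chemotherapy cohorts
   with embedded ground truth.
3. `03_fit_wt_scenarios.R` — multistart fits of all five scenarios,
   AICc/Akaike-weight comparison, linearized uncertainty.
4. `04_fit_perturbations.R` — chemotherapy fits (young/old; slowed TAP
   cycling, deeper quiescence in the old) and the knockout fit.
5. `05_bayes_uncertainty.R` — variance-decay noise models, adaptive
   Metropolis posterior, posterior-predictive bands.

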
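# nscdyn

Quantitative analysis of adult neural stem cell (NSC) population dynamics
under interferon signalling, for systems biologists studying stem-cell
aging in the mouse ventricular–subventricular zone.

Adult NSCs shuttle between quiescence (qNSC) and an active, cycling state
(aNSC). `nscdyn` implements a two-compartment ODE model of their counts,

```
dq/dt = −r(t)·q + 2·b·ps·a
da/dt =  r(t)·q − ps·a
```

with activation rate `r(t)` (constant, or exponentially decaying
`r0·exp(−βr·t)` as quiescence deepens with age), cell-cycle progression
rate `ps = log 2/(17.5/24) ≈ 0.9506`/day (fixed from the 17.5-h cycle
length), and self-renewal probability `b` — constant, time-logistic
`b(t) = ½(1 + e^(−βb·t)(2·b0 − 1))` (rising to ½ with age), or
population-feedback `b(N) = 1 − 1/(1 + (kb·N)^nb)`. Each division
self-renews with probability `b` or releases two progenitors; the
progenitor flux is `2·ps·(1−b)·a`.

On top of the model the package provides:

* **Fitting** — multi-start (Latin hypercube) box-constrained weighted
  least squares against per-mouse totals and active fractions, weights =
  inverse group SD; model variants ranked by AICc; parameters can be free
  per genotype, shared across genotypes (e.g. a single Hill `kb` for wild
  type and interferon-receptor knockout), or fixed.
* **Intervention simulations** — switch the wild-type parameter functions
  to their knockout counterparts at an arbitrary age, score stem cells
  remaining at day 660 relative to wild type and life-long progenitor
  production (the flux integrated over days 0–700), and scan switch ages
  for the production optimum.
* **Auxiliary statistics** — the biphasic change-time test for signalling
  time courses (step regression with an AIC scan over change times plus
  one-way ANOVA), a 5'TOP motif classifier for mRNA 5'UTRs (cytidine
  followed by 4–14 pyrimidines), per-cell gene-signature scoring (counts
  per million, log1p, summed over a gene set) and top-n signature
  selection from a differential-expression table.
* **Synthetic data generators** for every input, so the full pipeline is
  testable without access to animal data.

## Worked example

```r
library(nscdyn)

truth <- reference_truth()   # reference wild-type / knockout parameter pair
traj <- simulate_nsc(truth$params$WT, truth$variants$WT,
                     times = seq(0, 700, by = 10))
tail(as_trajectory_table(traj), 3)
#>    time_days  qNSC  aNSC total fraction_active progenitor_flux
#> 69       680 170.1 1.238 171.3        0.007225           1.232
#> 70       690 169.6 1.194 170.8        0.006992           1.187
#> 71       700 169.1 1.152 170.3        0.006767           1.143
```

The wild-type pool falls from thousands of NSCs at two months to a
~170-cell plateau at 22 months, with under 1% of cells active. Fit the
model back to synthetic per-mouse observations:

```r
obs <- generate_observations(truth$params, truth$variants, seed = 1)
fit <- fit_nsc(obs[obs$genotype == "WT", ],
               fit_spec(truth$variants["WT"], n_starts = 8, seed = 1))
fit
#> NSC model fit: 5 free parameters, 30 observations
#>   weighted RSS = 26.3772, AICc = 8.6391
#>   best free parameters:
#>     r0[WT]         0.0569112
#>     beta_r[WT]     0.00217758
#>     b0[WT]         0.300709
#>     beta_b[WT]     0.00406276
#>     NSC0[WT]       5962.29
```

The estimates recover the generating values (`r0 = 0.065`, `b0 = 0.32`,
`NSC0 = 6000`) to within the scatter expected from 20% count noise on five
mice per age. Finally, scan induced-knockout interventions:

```r
scan <- optimal_intervention_scan(
  truth$params$WT, truth$variants$WT,
  truth$params$IFNAGR_KO, truth$variants$IFNAGR_KO,
  t_switch_grid = seq(0, 700, by = 25))
scan$optimum
#> [1] 400
subset(scan$table, t_switch %in% c(0, 400, 700))
#>    t_switch relative_stem_cells_at_660 lifelong_production
#> 1         0                     20.674               22440
#> 17      400                     48.565               26636
#> 29      700                    100.000               25720
```

Losing interferon signalling from birth (`t_switch = 0`) leaves 21% of the
wild-type stem cells at day 660 and cuts life-long progenitor output;
switching at day 400 — after the decaying wild-type activation rate has
crossed below the constant knockout rate — reactivates the preserved pool
and maximises life-long production, exceeding the pure wild-type total
(`t_switch = 700`, i.e. no intervention).

A thin command-line wrapper over the same functions is included at
`inst/scripts/nscdyn-cli.R` (subcommands `simulate`, `intervene`, `scan`,
`biphasic`, `top-classify`, `score`, `synth-obs`).

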
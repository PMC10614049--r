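# cfimpact

Quasi-experimental evaluation of community-forest (CF) conservation
effectiveness from annual tree-canopy-cover (TCC) and land-cover panels.

Community forests are zoned, community-managed forest areas used across the
tropics as a conservation instrument. Whether they prevent deforestation
and forest degradation is a causal question with a selection problem: CFs
are not sited at random, and the covariates that drive siting (terrain,
accessibility, initial forest condition) also drive forest loss. `cfimpact`
implements the full evaluation chain for this setting:

* **Sample frame** — forest/nonforest reclassification (natural +
  plantation forest = forest), exclusion masking (water, protected areas,
  concessions), sparse random pixel sampling, and border-buffer filtering
  (samples whose 5-ha / 126-m buffer crosses the study boundary are
  dropped).
* **Confounders** — nine per-sample covariates at the relevant
  establishment year, including Horn-method slope, Euclidean distances to
  roads/villages/district centers, 8-neighbor grid path distance to
  nonforest, and the forest proportion in the 5-ha buffer.
* **Phased matching** — establishment-year cohorts matched oldest first:
  exact matching on forest state at establishment plus 1:1
  nearest-neighbor propensity matching without replacement, each control
  usable once across all phases; balance screened by the standardized mean
  difference, SMD = (x̄_T − x̄_C)/s_T, with |SMD| < 0.25 acceptable.
* **Event panel** — outcomes realigned to event time t = year −
  establishment year (controls inherit their partner's year), pooled over
  the window all cohorts observe, and collapsed to the treated−control
  difference series D(t).
* **Inference** — interrupted time-series (segmented) regression

      D(t) = β₀ + β₁·t + β₂·POST(t) + β₃·t·POST(t) + e,   POST(t) = 1{t ≥ 1},

  with the establishment year (t = 0) coded pre-intervention; β₂ is the
  level change at establishment and β₃ the trend change. Post-establishment
  trend fits, establishment-year cohort regressions (D on t × establishment
  year; a negative interaction = declining effectiveness of newer CFs), and
  Mann–Kendall trend screens with Bonferroni correction round out the
  inference layer.

Because the national data sets such designs use cannot be shipped, the
package includes a first-class synthetic landscape generator
(`scenario_config()`, `simulate_landscape()`) with confounder-biased zone
placement and injectable level/trend/cohort effects, so the entire chain is
validated by parameter recovery. See the methods vignette
(`vignettes/community-forest-evaluation.Rmd`) for the model, the generator
design and its defaults.

## Worked example

```r
library(cfimpact)
res <- run_pipeline(run_config(study_scenario(seed = 1), forest_only = TRUE))
print(res)
```

```
<run_result> 18321 samples (4082 treated), 1842 pairs over phases 1997-2007
  pooled window [-8, 12]; excluded phases: 1998, 2002, 2003, 2004, 2005, 2008, 2009, 2010
  ITS tcc.all      level +1.939 (p=4.96e-10), trend +0.469 (p=3.49e-12)
  ITS forest.all   level -0.004 (p=0.955), trend -0.088 (p=4.45e-06)
```

`study_scenario(seed = 1)` simulates a 200 × 200 landscape (1989–2019, 40
zones established 1997–2010) with injected TCC effects of +2.0 (level) and
+0.5/yr (trend) and placement biased uphill and toward roads. The run
draws and filters ~18k samples, matches 1,842 treated–control pairs in the
phases whose post-matching balance passes the 0.25 screen, and the ITS on
the pooled TCC difference series recovers the injected effects (level
+1.94, trend +0.47). Matching brings the pooled imbalance down to
|SMD| ≤ 0.06 on every covariate:

```r
res$pooled_balance_post
#>                   covariate    smd defined n_treated n_control
#> 1             forest_at_est  0.000    TRUE      1842      1842
#> 2                 elevation -0.011    TRUE      1842      1842
#> ...
#> 9 forest_prop_buffer_at_est -0.028    TRUE      1842      1842
```

The forest-cover outcome carries no injected effect here, and its level
change is null as expected; its small negative post-trend is a deliberate
lesson built into the generator — the clearing hazard is *log*-linear in
road distance while the propensity model is linear, so a residual
functional-form confounding of order 0.1 pp/yr survives matching (see the
vignette's limitations section). The forest-throughout analysis (samples
forested in every year, rematched without the forest-state covariate)
shows the degradation-only effect:

```r
its_coef(res$forest_only$its, "cf_establishment")
#> forest-throughout ITS level change: 1.776 (p = 1.21e-05)
```

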
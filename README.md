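# dkafluids

Quantitative acid–base analysis of intravenous fluid therapy in the first six
hours of diabetic ketoacidosis (DKA).

DKA presents as an unmeasured-anion metabolic acidosis: β-hydroxybutyrate
accumulates and the strong ion gap (SIG) rises. Guideline fluid therapy leans
on 0.9% NaCl (Na 154 / Cl 154 mmol/L). Because that fluid's Na–Cl difference
is zero, resolving the ketoacidosis can be traded for an *iatrogenic
hyperchloremic* acidosis: serum chloride rises and base-excess chloride

```
BE_Cl = Na − Cl − 32   (mmol/L)
```

falls below zero, even while SIG improves. This package implements the
physicochemical toolkit needed to study that trade-off and a reproducible
synthetic cohort to exercise it when no patient data are available:

* **Acid–base calculators** (Stewart / Figge–Fencl): bicarbonate from the gas
  (`0.0307 × PaCO2 × 10^(pH − 6.1)`), albumin and phosphate weak-acid charges
  (`Alb × (0.123·pH − 0.631)`, `Pi × (0.309·pH − 0.469)`), the strong ion gap

  ```
  SIG = (Na + K + Ca + Mg − Cl − lactate) − HCO3 − AlbQ − PiQ
  ```

  base-excess chloride with its hyper/normo/hypochloremia classifier, Van
  Slyke standard base excess, and the guideline DKA case definition
  (glucose > 200 mg/dL, HCO3 < 15 mmol/L, pH < 7.3, urine ketones ≥ 2+).
* **Fluid accounting**: a registry of the common DKA fluids with per-litre
  Na/Cl content, volume-weighted mixing, per-patient electrolyte loads
  ("only from fluids"; NaHCO3/KCl additives tracked separately), and regimen
  classification into chloride-rich (GI, Na−Cl difference = 0) versus
  chloride non-rich (GII, difference > 32 mmol).
* **Cohort handling**: wide CSV schema, adult-DKA inclusion filters with an
  exclusion log, derived SIG/BE_Cl columns and six-hour deltas
  (`delta_X = X(6 h) − X(admission)`).
* **The statistical battery**: Shapiro–Wilk-gated Student's t / Mann–Whitney
  comparisons, chi-square / Fisher's exact for categories, Pearson
  correlation with ICU length of stay, multivariate OLS on LOS (with R² and
  Durbin–Watson), and exact two-sample t-test power from the noncentral t.
* **A synthetic two-arm generator**: coherent DKA admission panels (chloride
  solved so each panel hits a drawn SIG target), per-arm fluid regimens, a
  six-hour mass-balance evolution with Winter's respiratory compensation, and
  a ground-truth LOS model — so every downstream stage is testable against
  known generating values.

## Worked example

```r
library(dkafluids)

sim <- generate_cohort(synthetic_cohort_config(seed = 42))  # 22 GI + 13 GII
res <- run_analyze(sim$cohort, sim$administrations)

compare_groups(res$included, "becl_h6")
#> becl_h6: GI vs GII
#>   GI  -2.64 ± 6.71
#>   GII  3.88 ± 7.27
#>   test = student_t, p = 0.0111 *

res$counts$hyperchloremic_h6
#>   group  n count  pct
#> 1    GI 22    13 59.1
#> 2   GII 13     4 30.8

two_sample_t_power(21, 13, mean_diff = 9, sd = 3)
#> [1] 0.9999999998
```

The chloride-rich arm ends the sixth hour hyperchloremic (negative BE_Cl,
59% of GI patients below zero) while the chloride non-rich arm does not; the
t-test power line shows that a 9 mmol/L BE_Cl separation with sd 3 is
detectable with near-certainty even at 21 + 13 patients. `res$regression`
prints the LOS model (coefficients, 95% CIs, R², Durbin–Watson);
`run_analyze(..., out_dir = "report")` writes the comparison tables,
regression table and a JSON summary, and `run_simulate()` writes a cohort
bundle (`cohort.csv`, `administrations.csv`, `ground_truth.json`).

## Vignette

`vignettes/dka-fluid-therapy.Rmd` documents the model and its assumptions,
every tunable constant with units and defaults, what the synthetic generator
does and does not emulate, and the package's numerical conventions.
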
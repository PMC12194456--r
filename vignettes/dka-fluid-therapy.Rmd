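---
title: "Methods: physicochemical acid-base analysis of DKA fluid therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physicochemical acid-base analysis of DKA fluid therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkafluids)
```

## The problem and the model

Diabetic ketoacidosis is, in Stewart terms, an unmeasured-anion acidosis:
β-hydroxybutyrate is a strong anion that is not part of the routine
chemistry, so it appears as a positive strong ion gap. Fluid resuscitation
with 0.9% NaCl delivers sodium (useful for renal ketoanion excretion) but an
equal chloride load, which lowers the plasma strong ion difference and can
replace the resolving ketoacidosis with a hyperchloremic one. The package
quantifies both sides of that exchange with two scalar summaries per blood
gas panel:

* **Strong ion gap.** `SIG = SIDa − HCO3 − AlbQ − PiQ`, where
  `SIDa = Na + K + Ca + Mg − Cl − lactate` is the apparent strong ion
  difference and the buffer charges are the Figge linear models
  `AlbQ = Alb(g/L) × (0.123·pH − 0.631)` and
  `PiQ = Pi(mmol/L) × (0.309·pH − 0.469)`, with bicarbonate from
  Henderson–Hasselbalch, `HCO3 = S × PaCO2 × 10^(pH − pK)`. `SIG > 0`
  indicates unmeasured anions.
* **Base-excess chloride.** `BE_Cl = Na − Cl − 32` mmol/L. Negative values
  flag chloride excess relative to sodium; the zero point is taken as
  normochloremia and the two strict inequalities define hyper- and
  hypochloremia. `BE_Cl` is attractive precisely because it is insensitive
  to free-water effects: adding the same amount to Na and Cl leaves it (and
  SIG) unchanged.

Assumptions: panels are arterial; Ca and Mg enter the charge balance in
mEq/L (ionized-equivalent; `mmol_to_meq()` converts, since SIDa is a charge
sum, not a mass sum); all formula evaluations are returned unclamped, with
range validation happening at ingest rather than inside the arithmetic.

## Constants

| constant | default | units | note |
|---|---|---|---|
| CO2 solubility `S` | 0.0307 | mmol/L/mmHg | see below |
| pK | 6.1 | – | bicarbonate system |
| BE_Cl reference | 32 | mmol/L | Na−Cl in "balanced" plasma |
| albumin slope/intercept | 0.123 / 0.631 | per pH / – | Figge model |
| phosphate slope/intercept | 0.309 / 0.469 | per pH / – | Figge model |
| Van Slyke factor / HCO3 ref / pH slope | 0.9287 / 24.4 / 14.83 | – | SBE |

A solubility coefficient an order of magnitude smaller (0.003) sometimes
appears in print; it yields HCO3 ≈ 2.4 mmol/L at a normal gas, which is
physiologically impossible, so 0.0307 is the default and the value is
configurable through `acid_base_constants()` / `read_constants()` (flat JSON,
unknown keys rejected). The standard base excess is the classical Van Slyke
approximation: analyzers report closely related but not identical values, so
the cohort pipeline carries both the analyzer columns (`hco3_*`, `sbe_*`)
and the formula-derived ones (`hco3_calc_*`, `sbe_calc_*`) and never
overwrites one with the other.

## Fluid accounting conventions

The registry ships the ten fluids in common DKA use with per-litre Na/Cl
content. Two registry entries are knowingly inconsistent with their
conventional "difference" labels and are kept as concentrations, which are
the quantities mass balance actually needs:

* the craftwork fluid (935 mL 0.45% NaCl + 65 mL 8.4% NaHCO3) is registered
  at Na 143 / Cl 83, so its computed difference is 60 mmol/L, while mixture
  arithmetic from the recipe gives ≈137/72 (difference 65) and its customary
  label is 50; `mix_fluids()` exposes the recipe-derived composition;
* 20% human albumin is registered at Na 125 / Cl 100 (difference 25) even
  though it is conventionally grouped with the zero-difference fluids.

`electrolyte_load()` is strict "only from fluids": NaHCO3 boluses and KCl
additives never enter the Na/Cl load; additive chloride is carried in its own
column and merged only under `merge_additives = TRUE` for sensitivity
analysis. Regimen classification is exact-zero → GI, > 32 mmol → GII, and
anything between (or negative) is `unclassified` rather than forced into a
group — the gap is empty under both generator menus, but real data could
populate it.

## Statistical battery

Comparisons are gated per variable: Shapiro–Wilk in each group at p ≥ 0.05
selects the classical equal-variance Student's t-test (Welch by flag — the
choice of the pooled test is a convention, made explicit rather than
hidden), otherwise Mann–Whitney U; categorical variables use Fisher's exact
test whenever an expected cell count is below 5, otherwise chi-square. All
tests are two-sided at nominal α = 0.05 and no multiplicity correction is
applied; the report output records the test used per row so a reader can
re-gate. Constant-in-both-groups variables raise a degenerate-input error
instead of a p-value.

The LOS model is ordinary least squares with intercept on 12 default
predictors (age, BMI, APACHE II, SOFA and the six-hour deltas of pH×100,
PaCO2, HCO3, Na, Cl, lactate, SIG, glucose); the predictor list is an
argument because different sites may add scores or labs. delta-pH is
rescaled by 100 *before* fitting so its coefficient is per 0.01 pH unit.
Rank deficiency raises an error naming the aliased columns. R² and the
Durbin–Watson statistic (via `lmtest::dwtest`) are reported; coefficient
tables are linear-model effects with 95% Wald CIs, never odds ratios.

Two-sample t-test power is computed exactly from the noncentral t
distribution with `ncp = Δ/(σ√(1/n1 + 1/n2))`, summing both rejection
tails; `stats::power.t.test` (equal-n only, far tail dropped) serves as a
cross-check in the tests, together with a 10,000-replicate Monte-Carlo
oracle.

## The synthetic cohort generator

The generator's job is to produce data with the statistical structure the
analysis assumes, with known ground truth. What it emulates:

* **Admission**: pH ~ N(7.10, 0.10), PaCO2 ~ N(16, 5) truncated to
  [6, 32] mmHg, Na ~ N(134, 6), lactate lognormal with median 2, glucose
  lognormal with median 450 mg/dL, and a target SIG ~ N(19, 6) truncated at
  ≥ 5 mmol/L. Measured bicarbonate is *computed* from the gas (coherence),
  and chloride is *solved* from the SIG identity so each panel hits its
  drawn target exactly. Draws are rejected until the DKA definition holds;
  a configuration whose acceptance region is empty errors out after a
  bounded number of draws instead of spinning.
* **Regimens**: GI receives 0.9% saline, volume ~ N(2302, 1188) mL truncated
  above 300 mL, plus occasional zero-difference co-fluids (dextrose, 0.45%
  saline — deliberately not albumin, whose registered composition is not
  difference-zero); GII receives one of craftwork/Isolyte/Isolyte-S with the
  volume set from a drawn target regimen difference (lognormal, median
  144 mmol, truncated to [95, 263]) plus occasional saline. Classification
  back through `classify_regimen()` is asserted, not assumed.
* **Six hours**: a two-compartment-free mass balance. With distribution
  volume `V = 0.2 L/kg × weight`, infused volume `V_inf` retained at 0.6 and
  urinary excretion of 0.3 of the infused Na/Cl,
  `Cl_6h = (Cl_0·V + 0.7·Cl_load)/(V + 0.6·V_inf)` (Na analogous, including
  NaHCO3 bolus sodium). SIG decays exponentially at 0.12 /h (ketoanion
  clearance under insulin). SBE moves by ΔBE_Cl + cleared SIG + bolus
  alkali/V, and the consistent 6th-hour gas is solved from three
  simultaneous relations: inverted Van Slyke (HCO3 from SBE and pH),
  Winter's compensation `PaCO2 = 1.5·HCO3 + 8` — keeping each patient's
  admission deviation from Winter's line and adding N(0, 2 mmHg) noise — and
  Henderson–Hasselbalch. The scalar equation in pH is monotone, so the
  solver is a bracketed `uniroot` (tolerance 1e−12); with zero infusion,
  zero clearance and zero noise the admission panel is an exact fixed point
  of the whole construction.
* **Outcome**: `LOS = 2.0 + 0.2·ΔCl + 0.3·Δlactate + N(0, 0.5)` days,
  floored at 1. The floor truncates the error distribution slightly, which
  is why coefficient-recovery checks are stated as CI coverage rates rather
  than exact unbiasedness.

What it does **not** emulate: within-patient correlation between admission
variables beyond what the formulas force (SIG–lactate dependence, for
instance, is absent); insulin–glucose pharmacodynamics; potassium shifts
beyond a fixed mean drop; renal adaptation of chloride excretion; any
mortality or AKI process. Passing recovery tests therefore demonstrates
that the *pipeline* is correct under its assumed data-generating structure,
not that the structure matches real patients.

## Numerical and boundary conventions

* DKA definition: strict `>`/`<` on glucose, bicarbonate and pH; ketones
  ≥ 2 inclusive. Adult inclusion is strict `age > 18`.
* `BE_Cl = 0` is labelled normochloremic; the classifier partitions the
  line with no overlap or gap.
* Exact-zero regimen difference uses a 1e−9 mmol tolerance (pure float
  bookkeeping; zero-difference menus produce exact zeros anyway).
* CSVs are UTF-8, "." decimal, empty cells for missing; numerics are
  written with 17 significant digits so a write–read round trip is
  bit-exact, and integer-looking columns are canonicalised to doubles on
  read.
* Failure modes are classed conditions (`dkafluids_schema_error`,
  `dkafluids_degenerate_error`) so callers can distinguish bad input from
  degenerate statistics without parsing messages; report writers create
  their output directory and never leave partial bundles on error paths
  (all computation precedes the first write).

## Problem sizes in the test suite

The suite exercises the oracle equivalences at exhaustive-enumeration scale
(group sizes ≤ 6 for Mann–Whitney, 2×2 tables for Fisher), the SIG oracle
on 1,000 random panels at 1e−9, parameter recovery on 100 simulated cohorts
of 200 patients per arm, direction consistency on 20 such cohorts, and the
study-size behaviour (22 + 13) across 25–30 seeds. These sizes keep each
property estimate's Monte-Carlo error far from its acceptance margin while
the whole suite stays comfortably fast on one core.

## Known limitations

* The six-hour evolution is a calibration device, not a physiological
  model; its constants (retained fraction, excretion fraction, SIG
  clearance) are plausible round numbers, config-exposed, and should not be
  interpreted clinically.
* The Figge charge models are linear approximations valid near
  physiological pH; far outside it they can go negative, and the package
  returns those values unclamped by design.
* Analyzer-reported HCO3/SBE and the formula-derived values differ
  systematically at extreme gases; the pipeline reports both but takes the
  analyzer values as primary for cohort tables, matching clinical practice.
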
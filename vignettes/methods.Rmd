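---
title: "Methods: assay estimators, speciation and blood-partitioning models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assay estimators, speciation and blood-partitioning models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(papartition)
```

`papartition` characterizes two determinants of toxicokinetic behaviour for
pyrrolizidine alkaloids (PAs) and their N-oxides (PANOs): lipophilicity
(log P, the log10 n-octanol:water partition coefficient of the neutral
species) and blood partitioning (Rb, the blood-to-plasma concentration
ratio at equilibrium). Both are key inputs to physiologically-based
toxicokinetic (PBTK) models, which need them to predict tissue
distribution. The package implements the assay-based estimators, the
ionization math linking log P to the pH-dependent log D, two in-silico Rb
models, a deviation-based evaluation of predictions against experimental
values, and a synthetic data generator that makes the whole pipeline
testable without wet-lab data.

## Assay estimators

**Shake flask (log P).** Equal volumes of presaturated n-octanol and water
are equilibrated with the compound starting from either phase
(bidirectional design), and each phase is quantified by LC-MS/MS. Because
the volumes are equal and samples undiluted, peak areas are proportional
to concentrations, and each replicate yields

$$\log P = \log_{10} \frac{A_{\mathrm{octanol}}}{A_{\mathrm{water}}}.$$

`estimate_logp()` pools all replicates from both directions into one mean
and sample SD (n−1 denominator) — the convention used to report the
experimental values — while retaining per-direction means.
`direction_effect()` probes the assumption behind pooling: if
equilibration were incomplete or phase-specific bias present, the two
starting directions would disagree. The test is a two-sided Welch
two-sample t-test at α = 0.05; Welch was chosen (the design itself does
not prescribe a test) because it does not assume equal variances across
directions. With all-constant noise-free groups the t statistic is
undefined; the implementation then decides directly on the group means.

**Depletion assay (Rb).** Whole blood and a plasma reference receive the
same spike (primary level 1000 ng/mL; 4–500 ng/mL levels probe
concentration dependence). After incubation the plasma separated from the
blood is depleted relative to the reference by exactly the
blood-to-plasma ratio:

$$R_b = \frac{A_{\mathrm{plasma\ reference}}}{A_{\mathrm{equilibrated\ plasma}}}.$$

No hematocrit correction enters this estimator — the ratio of two plasma
measurements is hematocrit-free by construction; hematocrit appears only
in the simulator's physical floor and in the mechanistic model.
`concentration_dependence()` regresses per-replicate Rb on log10
concentration (OLS, slope test at α = 0.05) as a quantitative surrogate
for the visual assessment such experiments usually get.

**Method validation.** `validate_logp_method()` / `validate_rb_method()`
compare determined and literature values for a reference panel: OLS
R², per-compound accuracy (|Δ| ≤ 0.2 log units for log P; percent
deviation ≤ 10% for Rb) and precision (replicate RSD < 10%). RSD uses
|mean| in the denominator; for means within 1e−6 of zero it is reported
as `NA` rather than exploding, and the precision flag is not evaluated.
Literature values for reference substances are user-supplied
configuration, not packaged data.

## Speciation

PAs are weak bases (tertiary amine); PANOs protonate only under acidic
conditions. For a monoprotic compound the Henderson–Hasselbalch relation
gives the neutral fraction, and the distribution coefficient follows as

$$\log D(\mathrm{pH}) = \log P - \log_{10}\!\left(1 + 10^{(\mathrm{pH} - pK_a)\,\Delta i}\right),
\qquad \Delta i = +1 \text{ (acids)},\ -1 \text{ (bases)},$$

equivalent to assuming the ionized species has no organic-phase affinity
(`log_d()` is tested against that brute-force construction to 1e−9).
Zwitterions would need two pKa values; since no study compound is
zwitterionic, `log_d()` raises an explicit unsupported-case error rather
than guessing a functional form. Where a compound has several pKa values,
the registry stores the single most relevant one (strongest basic or most
acidic centre), matching the single-pKa transform.

The packaged registry's pKa column holds **representative placeholder
values**, not measurements: 6.0 for the alkaloids and 4.0 for the
N-oxides. These were chosen once to encode the qualitative behaviour that
matters — alkaloids ≥ 96% neutral under assay conditions yet still > 1%
ionized at pH 7.4 (so they classify as bases), N-oxides effectively
neutral at pH 7.4 — and are fully overridable through a user registry
CSV.

## In-silico Rb models

**Acid/base classification.** In the absence of data, Rb is commonly
taken as 1 for neutrals and bases and 1 − hct = 0.55 for acids and
zwitterions, which are excluded from the red-cell volume.
`classify_at_ph()` first resolves the effective class: a declared base
whose ionized fraction at the prediction pH falls below 1% behaves as a
neutral and is reclassified. The 1% cutoff is a stated package choice;
only the qualitative classification (PA = base, PANO = neutral at pH
7.4) is externally given, and both classes map to Rb = 1 anyway, so the
cutoff does not affect the study compounds.

**Mechanistic model.** Red-cell affinity is approximated by the cell's
composition,

$$K_{rbc,pla} = f_{water} + f_{lipids}\,10^{\log P} + f_{prot}\,K_{prot},$$

and Rb follows from the whole-blood mass balance
$C_{blood} = (1-hct)\,C_{plasma} + hct\,K_{rbc,pla}\,f_{u,p}\,C_{plasma}$:

$$R_b = 1 + hct\,(K_{rbc,pla}\, f_{u,p} - 1).$$

This form reproduces the two anchoring limits — full exclusion from the
cells ($K = 0$) gives $R_b = 1 - hct$, and $K f_{u,p} = 1$ gives
$R_b = 1$ — and is asserted exactly in the tests. The composition
constants are not compound data and are typically buried inside PBTK
platforms; the packaged defaults (`blood_params()`: water 0.63, lipids
0.005, protein 0.33, $K_{prot}$ 0.2, hct 0.45) are representative human
erythrocyte values chosen once and shipped as a clearly separate,
overridable YAML file. Back-calculating a single consistent
parameterization from published per-compound mechanistic predictions is
not possible without compound-specific ionization handling, so those
predictions are treated as an approximate envelope (every default-
parameter prediction within 50% of experiment), not an exact target.

The lipid term uses $10^{\log P}$ of the neutral species literally. An
optional `ionization_correction` flag scales the lipid term by the
neutral fraction at the prediction pH — the physically motivated variant,
useful for sensitivity analysis — and is off by default for fidelity to
the standard composition model.

## Evaluation bands

`logp_deviations()` reports the signed deviation (predicted −
experimental, log units) banded at 1 log unit with direction; "< 1 log
unit" is strict and the threshold itself counts as ≥ 1, so a deviation of
exactly 1.01 lands in the upward band. `rb_deviations()` reports the
percent deviation $100\,|pred - exp|/exp$ banded strictly below 10% and
at 50%; the denominator is the experimental value, which is the
convention that reproduces the per-compound classifications of the
packaged tables. The symmetric fold deviation $\max(p/e,\,e/p)$ is
reported alongside but not banded. Band denominators count only
available predictions — methods that cannot predict N-oxides are judged
on the compounds they do cover. `summarize_experiment()` adds extremes,
N-oxide-minus-parent differences (reported signed) and the ascending
lipophilicity ranking of the parent alkaloids.

## Synthetic data generator

`simulate_shake_flask()` implements the equal-volume two-phase mass
balance: with $P = 10^{\log P}$, equilibrium mass fractions are
$P/(1+P)$ (octanol) and $1/(1+P)$ (water); replicates start with all
compound in one phase and move `equilibration_fraction` of the way to
equilibrium (a single mixing fraction, not time-resolved kinetics —
sufficient to probe the directional bias the bidirectional design exists
to detect). Mass is conserved exactly for every fraction.
`simulate_depletion()` generates reference plasma at the spike
concentration and equilibrated plasma at spike/Rb, rejecting truths below
the physical floor $1 - hct$.

Measurement noise is multiplicative lognormal on peak areas — the
standard model for LC-MS response — parameterized so `noise_cv` is
approximately the relative SD of an area; defaults mirror the study
design (CV 5%, n = 3 per direction, n = 6 depletion replicates,
1000 ng/mL primary level, hct 0.45). The generator does not emulate
chromatographic integration, carryover, LOQ censoring or plasma-protein
binding as a separate process (the depletion assay estimates Rb without
decomposing it), so passing recovery tests demonstrate estimator
correctness under the stated noise model, not robustness to every
artifact of real LC-MS data.

## Problem sizes and numerical choices

The packaged recovery studies use 500 simulated datasets per true value
(log P over {−2…2}: pooled-estimate MAE ≤ 0.05 at CV 5%; Rb over
{0.55…2.0}: mean bias within 3% at CV 5%), and 1000 null datasets per
type-I-error check (both tests held at 0.05 ± 0.02) — sizes at which the
binomial noise of a rejection-rate estimate (±0.007 SD) is well inside
the asserted band. Determinism: every generator accepts a seed;
validation panels derive per-compound seeds as `seed + index` so panel
members are independent but reproducible; `run_full_report()` writes all
files atomically (write-then-rename) and records the seed in its
summary header.

## Worked example

```{r example}
t1 <- pa_table1()
t2 <- pa_table2()

dev_logp <- logp_deviations(t1, logp_predictions_from_table(t1))
band_counts(dev_logp, "kowwin")

preds <- predict_rb_table(pa_compounds(),
                          fu_p = pa_fu_p(),
                          logp = setNames(t1$logp_exp_mean, t1$compound))
dev_rb <- rb_deviations(t2, preds[preds$method == "mechanistic", ])
summary(dev_rb$pct_dev)
```

## Known limitations

* Single-pKa speciation only; zwitterions and polyprotic compounds are
  rejected, not approximated.
* The mechanistic model covers red blood cells only — no other tissue
  partition coefficients — and its composition defaults are
  representative, not fitted; predictions inherit their uncertainty.
* The concentration-dependence and direction tests are null-hypothesis
  screens: a non-significant result at n = 6 is weak evidence of
  absence.
* Fixture tables carry experimental summary statistics (mean ± SD), not
  raw replicates; replicate-level analyses need user CSVs or the
  simulator.
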
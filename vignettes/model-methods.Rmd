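---
title: "A decision-analytic cost-utility model for early autism diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-analytic cost-utility model for early autism diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdascea)
```

# The decision problem

`tdascea` compares two ways of diagnosing autism spectrum disorder (ASD)
in children aged 1–5 referred with suspected developmental delay: a
structured diagnostic scale administered by trained providers ("TDAS")
and standard clinical diagnosis under DSM-5 ("ClinDx"). The comparison is
a cost-utility analysis from the societal perspective: lifetime costs in
USD (direct medical, direct non-medical, and caregiver/productivity
costs) against quality-adjusted life years (QALYs), summarized as an
incremental cost-effectiveness ratio (ICER)

$$\mathrm{ICER} = \frac{C_{\mathrm{TDAS}} - C_{\mathrm{ClinDx}}}
                       {E_{\mathrm{TDAS}} - E_{\mathrm{ClinDx}}}$$

on discounted totals, judged against a willingness-to-pay (WTP) threshold
of 160,000 THB/QALY (≈ 4,572 USD/QALY at 34.995 THB/USD).

# Model structure

The model is a hybrid of a one-shot **diagnostic decision tree** and a
lifetime **Markov cohort model**.

**Diagnostic phase.** In the TDAS arm a child tests positive with
probability 0.8990; positives split into true positives and false
positives; true positives enter ASD care classified mild / moderate /
severe at the chart-review mix (0.1111 / 0.5069 / 0.3819); false
positives are non-ASD. A small fraction of test-negatives (0.0071) is
diagnosed only after age five ("delayed diagnosis") and enters as severe.
In the ClinDx arm 0.6731 are diagnosed; 20% of the diagnosed are delayed
(entering severe) and the rest split at the ClinDx mix
(0.0608 / 0.3311 / 0.6081); the undiagnosed are non-ASD.

The published true-positive/false-positive pair (0.8286, 0.1961) sums to
1.0247 — the two figures come from different denominators. The default
reading rescales the pair to a branch distribution among test-positives
(0.8086 / 0.1914), which keeps the tree proper without requiring a
prevalence input. A prevalence-explicit alternative (treating 0.1961 as
one minus specificity) is available via
`flags$tree_interpretation = "prevalence"`; it needs
`flags$asd_prevalence` and is off by default because no prevalence for
the suspected cohort is published.

**Follow-up phase.** A five-state Markov model — non-ASD, mild, moderate,
severe, dead — with one-year cycles from the mean diagnosis age (3.52
years) to a closure age of 100. Annual severity transitions come from the
chart review (e.g. moderate→mild 0.2643, severe→moderate 0.2078);
severity at entry otherwise persists. Death is age-dependent: the annual
background probability $q(a)$ from a period life table, multiplied by a
relative risk of 2.370 in the ASD states. The composition is
mortality-first — die with $\min(1, q(a)\cdot RR)$, then survivors
redistribute across severities — which keeps every row stochastic for any
$q$. Rewards use start-of-cycle occupancy; a half-cycle correction is
available (`flags$half_cycle_correction`) but off by default, favouring a
simple, exactly reproducible trace. Costs and QALYs are discounted at 3%
per year with cycle 0 undiscounted.

**Accounting for non-ASD children.** Children ruled out at the diagnostic
phase stay in the trace (so cohort mass is conserved and both arms
compare the same suspected cohort) but by default accrue neither costs
nor QALYs: the analysis accounts lifetime outcomes for the diagnosed ASD
cohort only, which is the accounting the reference per-strategy totals
imply. Setting `flags$u_non_asd = 1` instead credits ruled-out children a
utility of 1 under background mortality; note that under that accounting
the strategy diagnosing *more* children necessarily loses QALYs relative
to its comparator, reversing the sign of the incremental QALYs.

# Costing

Each severity state carries an annual societal cost assembled from the
published components:

* outpatient treatment (66 / 133 / 124 USD/yr for mild / moderate / severe);
* inpatient treatment: per-admission cost (387 / 416 / 664 USD) times the
  severity-specific annual admission probability;
* additional activities (1314 / 1148 / 1152 USD) times the attendance
  proportion (0.2114 / 0.2243 / 0.4561);
* therapy instruments (11 / 197 / 199 USD) times the purchase proportion,
  charged **once at model entry** by default (`flags$instrument_mode`),
  since a purchase is an acquisition rather than an annual flow;
* travel, food and accommodation around outpatient visits (visits/year ×
  73.4 USD including the caregiver's accompaniment cost) and admissions;
* caregiver costs at home: hired caregiver salary × hired proportion plus
  forgone income (518 USD/yr) × the severity-specific quitting proportion.

The survey reports the *overall* admission probability (0.3460) and the
severity composition of the admitted (0.0585 / 0.3032 / 0.6383), not
admission conditional on severity. The package Bayes-inverts:
$P(\text{admit}\mid s) = P(\text{admit}) \, P(s \mid \text{admit}) / P(s)$,
with $P(s)$ taken as the equal-weight average of the two chart-review
mixes (configurable via `flags$admission_cohort_mix`). The identity
$\sum_s P(s) P(\text{admit}\mid s) = P(\text{admit})$ holds exactly and
is tested.

Diagnostic-phase costs are charged once per entrant: labor per diagnosis
(monthly labor cost over 2 diagnoses/week × 52/12), and for TDAS the
training (151 USD) and instrument (323 USD) outlays amortized over 104
diagnoses per provider-year plus annual maintenance (0.27) and cloud
(1.43) charges — 21.72 USD/patient against 7.04 USD for ClinDx.

# Uncertainty analysis

**Distributions.** Probabilities and utilities are Beta, severity mixes
Dirichlet, costs and visit counts Gamma, and the mortality relative risk
Log-normal, all fitted by the method of moments to the published
mean/SE. Inputs published only with a "±20%" variation get a dispersion
of `default_cv × mean` with `default_cv = 0.20`. The Dirichlet effective
sample size uses the smallest per-component $m(1-m)/se^2$ — the most
conservative (widest) choice consistent with every published SE; the
chart-review sample sizes (147/148) are available via
`flags$dirichlet_neff = "counts"`. The relative-risk SE is read on the
natural scale (all other rows are natural-scale pairs); a log-scale
reading is available via `flags$rr_se_scale`.

**PSA.** 10,000 iterations by default; each draws every non-fixed input
jointly (Dirichlet triples summing to one exactly), reruns the tree,
cohort and accrual for both arms, and records discounted (ΔC, ΔE). Draws
with infeasible severity transitions (row sum above one) are re-drawn,
capped at 100 attempts. Summaries never average raw ICERs: the
cost-effectiveness acceptability curve (CEAC) and the quadrant shares are
computed from net monetary benefit, $\mathrm{NMB} = \lambda\,\Delta E -
\Delta C$. The default CEAC grid spans 0–10,000 USD/QALY in steps of 100,
covering both the base-case ICER and the policy threshold.

**One-way analysis.** Each non-fixed input moves to
$\text{mean} \pm 1.96\,se$ (or ±20% without an SE), clamped to its
support; severity-mix components move one at a time with the other two
renormalized to preserve their ratio. The tornado table records the ICER
at both bounds sorted by excursion width; an excursion that flips the
comparison into dominance (ICER undefined on one side) is ranked as
maximally influential.

**Scenario analysis** swaps the ClinDx severity mix for
(0.1139, 0.4557, 0.4304), the shares re-estimated without the specialty
hospital, and changes nothing else.

# The life table

The model needs annual all-cause death probabilities by age, which no
input table in the source material provides. The bundled file
`life_table_thai_synthetic.csv` is a **synthetic stand-in, not official
data**: a Gompertz–Makeham hazard with an infant component,
$h(a) = A + B e^{\gamma a} + I e^{-k a}$, calibrated once so that life
expectancy at birth is 75.3 years and infant mortality 8 per 1000 —
published Thai summary indices. For policy use, supply a real national
period table via `load_params(..., life_table = "your_table.csv")`; all
results are reported against the configured table. The generator
`make_life_table()` builds simpler pure-Gompertz tables (defaults
`c = 1e-4`, `gamma = 0.09`) for testing.

# Synthetic data generators

The original inputs come from a five-hospital chart review (n = 295) and
a caregiver survey (n = 295) that are not redistributable. The package
generates data with the same statistical structure so the estimation →
model pipeline can be exercised and tested end to end:

* `simulate_chart_review()` draws entry severities from a mix and moves
  patients annually at the true transition probabilities;
  `estimate_transition_rates()` recovers annual risks as
  events / person-years with binomial SEs. The original "survival
  analyses" are emulated as discrete annual-risk estimation, matching the
  model's one-year cycles (only annual probabilities are published).
  Follow-up length is a parameter, as the real review's censoring
  structure is unreported.
* `simulate_cost_survey()` draws itemized Gamma costs and Beta utilities
  at the published moments and returns sample moments for recovery
  comparisons.

What the generators do *not* emulate: between-hospital heterogeneity,
within-patient correlation of cost items, measurement error in severity
staging, and informative censoring. Passing recovery tests therefore
shows the estimators and pipeline are coherent, not that the original
data would reproduce.

# Numerical conventions and edge cases

* Ages are looked up at the integer part of the attained age
  (3.52, 4.52, … → 3, 4, …); at and beyond the closure age, $q = 1$.
* The horizon has `max_age − floor(start_age)` = 97 cycles; a zero-cycle
  horizon returns the entry row and accrues only one-time costs.
* A Beta fit requires $se^2 < m(1-m)$; an infeasible pair raises an
  error rather than silently truncating.
* ICERs are reported only when the quadrant makes a ratio meaningful;
  otherwise the comparison is labelled dominant / dominated / equal.
* All analyses are deterministic given the configuration and seed;
  `run_full()` writes a manifest (config hash, seed, flags, files) so a
  rerun can be verified bit-for-bit.

# Problem sizes used in the tests

The bundled analyses run the 97-cycle cohort model; the probabilistic
analysis uses the configured 10,000 iterations; parameter-recovery tests
simulate 2,000 patients over 10 years (≈ 20,000 person-years), sized so
binomial confidence intervals are tight enough to detect estimator bias
while keeping the suite quick.

# Known limitations

* The follow-up phase has no treatment-effect modelling: severity
  movement and costs are the same in both arms after entry, so all
  benefit flows through the entry distribution.
* Delayed diagnoses enter as severe immediately at cycle 0; there is no
  explicit pre-diagnosis waiting sub-model.
* False positives accrue no ASD costs and no workup cost by default
  (`flags$fp_workup_cost` adds a one-time charge).
* The two arms imply different effective ASD prevalence in the same
  suspected cohort; the published figures are implemented as printed.
* Headline incremental results are sensitive to the accounting choices
  documented above (non-ASD accrual, tree interpretation, participation
  proportions in the costing) and to the life table; every such choice is
  a logged configuration flag so differences can be attributed.
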
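---
title: "Reliability of multi-scanner brain volumetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability of multi-scanner brain volumetry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volagree)
```

## The measurement problem

Automated brain segmentation turns a T1-weighted MR image into regional
volumes, but the numbers depend on the scanner (vendor, model,
acquisition protocol) as well as on the anatomy. A scan–rescan study —
each subject scanned twice per scanner on several scanners — lets the
observed variance be split into what distinguishes subjects and what is
measurement error, and lets the error itself be split into replicate
noise and scanner-associated effects. `volagree` packages that analysis
for long-format volume tables keyed by (subject, scanner, run, software,
structure, lesion-filled flag), with TIV (total intracranial volume)
carried per record for head-size normalization.

Two conventions are hard-wired as defaults, both overridable: ICC and
the scanner-bias tests run on **raw** volumes (so that an imperfect
normalization cannot masquerade as scanner disagreement), while variance
components, SEM/SDC and power planning run on **TIV-normalized**
volumes (the standard cross-sectional practice). `summarize_reliability()`
and `power_table()` normalize internally when handed a raw table;
`pivot_ratings()` warns if asked to build ICC input from normalized
values.

## Agreement: ICC(A,1) and ICC(C,1)

Both ICCs come from the two-way mean squares of the n-subject by k-rater
matrix without replication (rows MSR, columns MSC, residual MSE):

- consistency, `ICC(C,1) = (MSR - MSE) / (MSR + (k-1) MSE)`, ignores
  fixed rater offsets — a scanner that reads uniformly 3% low does not
  lower it;
- absolute agreement,
  `ICC(A,1) = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
  charges such offsets to the denominator.

Within-scanner agreement (scan vs rescan) is reported as ICC(A,1);
between-scanner agreement (first-run values) as ICC(C,1), for every
scanner pair and for all scanners jointly — pairwise values are the
primary reporting unit, the joint value a summary. Confidence intervals
are the exact F interval for (C,1) and the Satterthwaite-approximated F
procedure for (A,1) (McGraw & Wong). Design choices worth stating:

- *Single-measurement forms only.* A clinical measurement is one scan;
  average-measure ICCs would answer a different question.
- *Two-way random effects* for both models: runs and scanners are
  treated as samples of possible measurement occasions, which is the
  basis for generalizing beyond the three scanners at hand.
- *Negative estimates* are reported as computed (not floored at zero)
  and classify as "poor". Classification bands are lower-inclusive:
  values in [0.5, 0.75) are moderate, [0.75, 0.9) good, 0.9 and above
  excellent.
- *Listwise deletion* per ratings matrix: a subject missing any rater
  value is dropped from that matrix only, and the dropped count is kept
  so that rows + dropped always equals the design size.

The identity `ICC(A,1) <= ICC(C,1)` holds whenever the estimated rater
variance is non-negative (`MSC >= MSE`) *and* the common numerator
`MSR - MSE` is non-negative; for negative numerators (subjects
indistinguishable) the inequality reverses sign, which the property
tests guard for explicitly.

## Variance components, SEM and SDC

Per (software, structure) cell the model is the crossed layout

```
value_ijr = mu + subject_i + scanner_j + (subject x scanner)_ij + e_ijr
```

fitted by expected-mean-squares moments when every subject-by-scanner
cell has the same number of runs, and by REML (`lme4::lmer` with
tightened bobyqa tolerances) otherwise — on balanced data with interior
estimates the two coincide, which the tests verify to 1e-6. Negative
moment estimates are truncated at zero and flagged.

The reported scanner variance folds the subject-by-scanner interaction
into the scanner term (`interaction = "fold_into_scanner"`), because
both contribute to between-scanner but not within-scanner error; the
`pool_into_residual` and `drop` policies are available for sensitivity
analysis. The derived statistics, as percentages of the cell mean, are

```
SEM_within  = 100 * sqrt(sigma2_e) / Vbar
SEM_between = 100 * sqrt(sigma2_r + sigma2_e) / Vbar
SDC         = 1.96 * sqrt(2) * SEM
```

so `SEM_between >= SEM_within` by construction and `SDC / SEM` is the
constant 2.771859... to machine precision. Percent-of-mean outputs are
invariant to multiplying all volumes and TIVs by a positive constant.
Lesion-filled and non-filled tables are analysed separately per flag.

## Scanner bias

`omnibus_scanner_test()` takes complete-case first-run values across the
scanners and runs a one-within-factor repeated-measures ANOVA when the
within-subject residuals pass a Shapiro–Wilk gate at alpha = 0.05, else
a Friedman test. The RM-ANOVA p-value is Greenhouse–Geisser corrected by
default (a conservative choice with k = 3 levels; switchable to
`sphericity = "none"`). Post-hocs are paired t or Wilcoxon signed-rank
to match the omnibus branch, Bonferroni-corrected over the scanner pairs
of that one cell — no correction is applied across structures or
software, matching how per-cell pairwise annotations are usually drawn.
By default post-hocs run when the omnibus rejects
(`posthoc = "if_significant"`); the gate decision is recorded on the
result. `bland_altman()` reports the mean paired difference (fixed
bias), 1.96-SD limits of agreement with t-based CIs, and the slope of
difference on pair mean (proportional bias); zero-variance differences
yield a zero slope with a degeneracy flag rather than an error.

## Power planning

`sample_size_two_group()` iterates the exact noncentral-t power of the
two-sided, equal-variance two-sample t-test to the smallest integer n
per group (floor n = 2) reaching the target power; the z-approximation
is available and understates n slightly (15.7 vs 17 at unit effect and
unit SD). `power_pair()` evaluates it twice per cell: with total SD
`sqrt(sigma2_s + sigma2_e)` for a within-scanner design and
`sqrt(sigma2_s + sigma2_r + sigma2_e)` for a between-scanner design,
reporting both integer sizes, their ratio, and the continuous
variance ratio. The subject variance comes from the same cell's fitted
decomposition unless overridden.

## The synthetic cohort generator

The generator draws

```
volume_ijrs = mean_s * head_i * subj_is * bias_js * inter_ijs * noise_ijrs
```

with unit-mean lognormal factors (a CV of c corresponds to
`sigma^2 = log(1 + c^2)` on the log scale): `subj` is between-subject
anatomy beyond head size, `bias_js` a fixed multiplicative scanner
effect, `inter` subject-by-scanner variation, `noise` replicate error.
TIV is drawn once per subject (true anatomy, constant across scanners
and runs) and structure volumes scale proportionally with it
(`tiv_scaling = 1`), so TIV-normalization removes head-size variance
exactly — as it is intended to in real data — and `subject_cv` is the
variation that survives normalization. On the log scale the model is
exactly the additive crossed layout, which is what makes closed-form
parameter-recovery checks possible: the estimand of the scanner
component under fixed biases is the sample variance of the log biases.

The preset (`preset_cohort_config()`) encodes the emulated study design:
21 subjects, scanners GE/Philips/Toshiba, 2 runs, 11 structures (whole
brain, GM, WM, CSF and seven bilateral deep grey matter structures),
one missing acquisition (subject 1, GE, run 2 — a rescan lost to
motion), and GE tissue-class biases of +2% GM and -3% WM. Parameter
provenance:

- *subject_cv = 4.6%*: back-calculated from published between-scanner
  sample-size requirements — a between-scanner n of 642 per group to
  detect a 1% difference at 80% power implies a total SD near 6.4% of
  the mean, and removing a between-scanner SEM of 4.39% leaves a subject
  SD near 4.6%. No between-subject variance is published directly, so
  this is a documented stand-in, not a claim about the cohort.
- *Structure means* are plausible adult bilateral volumes (brain
  1,050,000 mm^3 down to accumbens 1,000 mm^3); they are free
  parameters, and every reported statistic is scale-invariant anyway.
- *Residual CVs* grow from 0.5% (whole brain) to 3% (accumbens),
  reflecting that small structures are harder to segment repeatably.
- *Bias directions* (GM high, WM low on GE) follow published findings;
  the magnitudes are free parameters of the generator.
- *interaction_cv = 0.5%* keeps a small but non-zero subject-by-scanner
  term so that the folded scanner component is exercised.

What the generator does **not** emulate: correlation of subject effects
across structures (each structure draws independently — harmless here
because every statistic is computed per structure), segmentation
failures and outliers, lesion effects on segmentation, cross-software
TIV discrepancies (it models one software at a time), and any
proportional (volume-dependent) scanner bias — planted biases are purely
multiplicative, so Bland–Altman slopes are null in expectation. Passing
tests therefore demonstrate correctness of the statistical machinery
under the stated model, not robustness to those real-data features.

## Numerical choices and degenerate inputs

- Moments vs REML switch automatically on balance; requesting moments on
  unbalanced data is an error rather than a silent approximation.
- lme4 is run with bobyqa and `rhoend = 1e-12` so that balanced-data
  REML agrees with the closed-form moments to ~1e-9 absolute.
- An all-constant cell yields zero variance components, a null Friedman
  result (statistic 0, p = 1) and ICCs reported as undefined errors —
  never NaNs.
- Constant paired differences give `sd_diff = 0`, degenerate (zero)
  Bland–Altman slope with a flag, and limits of agreement equal to the
  bias.
- The ratings-matrix floor is 3 complete subjects and 2 raters;
  classification requires ICC <= 1 and tolerates the floating-point
  boundary.
- Exclusion keys that match nothing warn and are logged, not fatal, so a
  QC list can be applied to a partial table.

## Simulation sizes used by the test suite

The shipped checks use problem sizes chosen to estimate each property
with comfortable Monte-Carlo margins while keeping the default run
brisk: 500 replicate cohorts (21 x 3 x 2, single structure) for
moment-estimator recovery within 3 Monte-Carlo SEs, 50 replicates for
the moments-REML identity, 500 replicates each for the type-I error
band [0.03, 0.07] and for the >= 95% detection rate of the planted 3%
GE WM deficit, 2000 replicates for the empirical-power band
[0.78, 0.86], and 20 random matrices against the independent ICC
reference implementation at 1e-6.

## Known limitations

- Cross-sectional only: no longitudinal (percent brain volume change)
  modelling, no slopes over time, and no cluster/multi-site design
  effects in the power module.
- The between-scanner ICC treats the three scanners as exchangeable
  random raters; with k = 3 the scanner variance is estimated on 2
  degrees of freedom and is accordingly noisy — SEM_between intervals
  are wide in any study of this size.
- Published SEM/SDC reference values are printed rounded to two
  decimals, so consistency checks against them carry a +-0.05 band.
- The Shapiro–Wilk gate and the Greenhouse–Geisser correction are
  reasonable defaults, not reconstructions of any particular study's
  unstated choices; both are recorded in the result objects.
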
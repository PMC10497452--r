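# volagree

Cross-sectional test–retest reliability analysis for brain volumetry
measured on multiple MR scanners.

When the same person is scanned twice on the same scanner ("scan–rescan")
and again on scanners from other vendors, the resulting regional volumes
disagree for two distinct reasons: replicate measurement noise and
systematic scanner effects. Quantifying both matters for anyone using
automated segmentation to track atrophy — for example in multiple
sclerosis, where true brain volume loss is on the order of 0.5–1.35% per
year and can be smaller than the measurement error between scanners.
`volagree` implements the standard statistical toolkit for such studies
as a pipe-friendly, tibble-in/tibble-out R package, plus a synthetic
cohort generator so the whole pipeline is testable without patient data.

## What it computes

For each (segmentation software, brain structure) cell of a long-format
volume table:

- **Agreement** — single-measurement intraclass correlations under the
  two-way random-effects layout: ICC(A,1) for absolute agreement between
  scan and rescan within one scanner, and ICC(C,1) for consistency
  between scanners on first-run values, each with the F-based 95% CI
  (McGraw & Wong) and the conventional poor/moderate/good/excellent
  classification (0.5 / 0.75 / 0.9 cut-points).
- **Variance components** — the crossed random-effects decomposition
  `y_ijr = mu + subject_i + scanner_j + (subject x scanner)_ij + e_ijr`,
  by expected-mean-squares moments on balanced data and REML (lme4)
  when runs are missing.
- **Measurement error** — the standard error of measurement as a
  percentage of the mean, `SEM_within = 100 * sqrt(sigma2_e) / Vbar` and
  `SEM_between = 100 * sqrt(sigma2_r + sigma2_e) / Vbar`, and the
  smallest detectable change `SDC = 1.96 * sqrt(2) * SEM`.
- **Systematic bias** — repeated-measures ANOVA
  (Greenhouse–Geisser-corrected) or Friedman test across scanners, with
  Bonferroni-corrected paired post-hocs, and Bland–Altman fixed- and
  proportional-bias statistics per scanner pair.
- **Power planning** — minimum per-group n for a two-sided two-sample
  t-test to detect a stated percent volume difference (default 1% at
  alpha = 0.05, power 0.80) under within-scanner vs between-scanner
  measurement variance, and their ratio.

## Worked example

```r
library(volagree)
library(dplyr)

# a synthetic stand-in for a 21-subject, 3-scanner, scan-rescan MS cohort
cohort <- generate_cohort(preset_cohort_config(seed = 1),
                          software = "toolA")

# scan-rescan agreement for the thalamus on the GE scanner
m <- pivot_ratings(cohort, "toolA", "thalamus", "within", scanner = "GE")
icc_absolute(m)
#> ICC(A,1) = 0.9213  95% CI [0.8140, 0.9680]  (excellent)
#>   n = 20 subjects, k = 2 raters, 1 dropped
```

One subject's GE rescan is missing by design (the preset emulates a run
excluded for motion), so the ratings matrix has 20 rows and reports one
dropped subject. An ICC of 0.92 means subjects remain well
distinguishable despite scan–rescan noise.

```r
rel <- summarize_reliability(cohort)   # normalizes by TIV internally
rel %>%
  select(structure, sem_within_pct, sem_between_pct, sdc_between_pct) %>%
  filter(structure %in% c("brain", "gm", "wm", "thalamus"))
#>   structure sem_within_pct sem_between_pct sdc_between_pct
#> 1 brain               0.51            0.65            1.79
#> 2 gm                  0.56            1.38            3.83
#> 3 wm                  0.81            1.87            5.18
#> 4 thalamus            1.34            1.37            3.80
```

The preset plants a +2% GM and -3% WM bias on the GE scanner: for those
tissues SEM_between is two to three times SEM_within, and a WM change
smaller than 5.2% of the mean cannot be told apart from measurement
error when scans come from different vendors.

```r
power_table(cohort) %>%
  filter(structure %in% c("brain", "wm")) %>%
  select(structure, n_within, n_between, ratio)
#>   structure n_within n_between ratio
#> 1 brain          223       226  1.01
#> 2 wm             596       641  1.08
```

Mixing scanners inflates the per-group sample size needed to detect a 1%
group difference, most where the scanner bias is largest.

`run_pipeline()` executes all stages end-to-end from a YAML/JSON config
(or an R-built `pipeline_config()`), writing tidy CSV tables and a
`manifest.json` with content hashes; a rerun with the same config and
seed is byte-identical. `plot_icc_heatmap()`, `plot_reliability_heatmap()`,
`plot_power_ratio()` and `autoplot()` on a Bland–Altman result give the
usual figures.

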
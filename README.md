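# gammacc

Case-control analysis of stimulus-induced gamma rhythms in scalp EEG.

Large grating stimuli induce narrow-band gamma oscillations — a slow
(20–34 Hz) and a fast (36–66 Hz) band — over occipito-parietal cortex.
`gammacc` implements the full analysis chain for asking whether elderly
subjects with mild cognitive impairment (MCI) or Alzheimer's disease (AD)
show weaker induced gamma than age- (±1 year) and gender-matched healthy
controls, and whether that weakening is gamma-specific (alpha suppression,
32 Hz SSVEPs, ERPs and oculomotor behaviour serving as negative controls).
It is written for electrophysiologists and methods researchers who want
every stage of such a study — montage, spectra, artifact rejection, eye
screening, matched statistics — as tested, composable functions.

The central statistic is the band-limited change in power

```
ΔPower = 10 · log10( Σ_f ST(f) / Σ_f BL(f) )   [dB]
```

with ST and BL the stimulus (250–750 ms) and baseline (−500–0 ms) spectra,
averaged across analyzable repeats and nine occipito-parietal bipolar pairs
before the single log ratio. Group inference pairs each case with the
averaged spectra of its matched controls: Kruskal-Wallis tests on medians,
±SD of 10,000 bootstrap medians, one-tailed JZS paired Bayes factors
(Cauchy prior scale 1), and the severity regression
`ΔPower = β0 + β_CDR·CDR + β_AGE·AGE + β_GENDER·GENDER + ε`.

Because raw cohort EEG is not desk-scale, the package includes a synthetic
cohort generator (1/f background, suppressible alpha, gated band-limited
gamma with group deficits, SSVEP, ERP, occipital topography, fixational eye
traces with microsaccades, blinks and pupil dynamics) so that every stage is
verifiable against known ground truth.

## Worked example

The numbered scripts under `analysis/` run a small demonstration study:

```sh
Rscript analysis/01_simulate_cohort.R    # 10 healthy + 3 MCI + 1 AD
Rscript analysis/02_subject_metrics.R    # per-subject ΔPower, SSVEP, ERP, eye
Rscript analysis/03_group_comparison.R   # matched case-control statistics
Rscript analysis/04_replicate_study.R    # seeded effect-pattern replicates
```

`02_subject_metrics.R` prints the per-group band summaries:

```
analyzed 14/14 subjects (0 excluded)
  healthy  slow gamma  7.07 dB, fast gamma  7.58 dB, alpha -1.11 dB (means, n=10)
  mci      slow gamma  3.57 dB, fast gamma  4.10 dB, alpha -1.50 dB (means, n=3)
  ad       slow gamma  1.19 dB, fast gamma  2.24 dB, alpha -1.31 dB (means, n=1)
```

Healthy subjects show the ~6–8 dB induced-gamma response the generator is
calibrated to; cases sit several dB lower in both gamma bands while alpha
suppression (negative ΔPower) is group-independent. `03_group_comparison.R`
then runs the matched statistics (MCI and AD pooled at this cohort size):

```
4 cases, each with >= 1 matched control
  alpha       case -1.45 vs control -1.01 dB | K-W H= 1.33 p=0.248 | BF10(left)=0.19
  slow_gamma  case  2.91 vs control  7.55 dB | K-W H= 5.33 p=0.021 | BF10(right)=485.99
  fast_gamma  case  3.35 vs control  7.94 dB | K-W H= 5.33 p=0.021 | BF10(right)=388.03
```

— the gamma-specific pattern: both gamma bands significantly lower in cases
with strong directional Bayes-factor support, alpha indistinguishable
(BF10 < 1 favours the null). Tables land in `results/`.

The same stages are available programmatically:

```r
library(gammacc)
montage <- derive_bipolar(build_layout())       # 112 pairs, 9-pair analysis set
params  <- gen_params(seed = 1)
cohort  <- generate_cohort(10, 3, 1, repeats_per_condition = 8,
                           params = params)
summaries <- cohort_summaries(cohort, default_config(seed = 1))
report    <- run_comparison(summaries, default_config(seed = 1),
                            case_groups = c("mci", "ad"))
```

## Package layout

- `R/` — montage, synthetic generator, artifact cascade, spectral
  estimators, eye analysis, statistics, pipeline orchestration
- `inst/extdata/` — packaged electrode layout and 112-pair bipolar montage
  (TSV)
- `analysis/` — the numbered demonstration study
- `vignettes/induced-gamma-case-control.Rmd` — model, assumptions,
  parameter choices, generator realism and limitations
- `tests/testthat/` — unit, property and acceptance tests
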
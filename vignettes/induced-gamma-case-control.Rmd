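---
title: "Stimulus-induced gamma as a case-control EEG marker: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stimulus-induced gamma as a case-control EEG marker: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gammacc)
```

## The analysis this package implements

Large, high-contrast grating stimuli induce narrow-band gamma oscillations
in visual cortex that are visible in scalp EEG over occipito-parietal
electrodes. In elderly cohorts these induced rhythms split into a slow
(20-34 Hz) and a fast (36-66 Hz) band. The scientific question the pipeline
addresses is whether subjects with mild cognitive impairment (MCI) or
Alzheimer's disease (AD) show weaker stimulus-induced gamma than healthy
subjects matched on age (within one year) and gender - and whether that
weakening is specific to gamma, rather than a broad change that would also
appear in alpha suppression, in steady-state visually evoked potentials
(SSVEPs), in event-related potentials (ERPs), or in oculomotor behaviour.

The per-subject statistic is the band-limited change in power

$$\Delta\mathrm{Power} = 10\,\log_{10}
  \frac{\sum_f \mathrm{ST}(f)}{\sum_f \mathrm{BL}(f)}\;\mathrm{dB},$$

where ST and BL are stimulus-window (250-750 ms after onset) and
baseline-window (-500-0 ms) power spectra, averaged across all analyzable
stimulus repeats and across nine occipito-parietal bipolar pairs, and the
sum runs over the frequency bins of the band, both edges included. The sums
are taken *before* the log ratio: a mean of per-bin dB values would weight
every bin equally, whereas this statistic deliberately lets the
higher-power low-frequency bins dominate.

Group inference is non-parametric. Each case is paired with the average
spectra of all of its matched controls; medians are compared with
Kruskal-Wallis tests, uncertainty is shown as the SD of 10,000 bootstrap
medians, and directional evidence is quantified with a JZS paired-t Bayes
factor (Cauchy prior scale 1; right-tailed for gamma, where the alternative
is control above case, left-tailed for alpha). Dependence on disease
severity is estimated with ordinary least squares:

$$\Delta\mathrm{Power} = \beta_0 + \beta_{CDR}\,CDR + \beta_{AGE}\,AGE +
  \beta_{GENDER}\,GENDER + \varepsilon,$$

with CDR the Clinical Dementia Rating, age in integer years, and gender
coded 0 for males and 1 for females.

## Montage

The packaged layout has 64 electrodes on the 10-10 grid. Bipolar
re-referencing derives 112 anode-minus-cathode pairs between neighbouring
electrodes from them; the pair list ships as a versioned data file
(`inst/extdata/bipolar_montage.tsv`) rather than being recomputed from
geometry, so it cannot drift between releases. The pairing convention is:
laterally adjacent electrodes within a row; same-column electrodes in
consecutive rows (the midline chain starts at AFz); and six posterior
diagonals (PO3-P3, PO4-P4, PO7-P7, PO8-P8, Iz-O1, Iz-O2) that close the
parieto-occipital lattice. Anodes are the more posterior (between rows) or
more medial (within a row) electrode. The exact neighbour rule used in the
original recordings is defined in prior work we could not consult, so this
list documents *our* adopted scheme; the nine analysis pairs - PO3-P1,
PO3-P3, POz-PO3; PO4-P2, PO4-P4, POz-PO4; Oz-POz, Oz-O1, Oz-O2 - are pinned
verbatim and validated at load time. Scalp coordinates are a schematic
azimuthal-equidistant-style projection used only for plotting.

## Spectral estimation

All spectra are single-taper multitaper estimates: the leading Slepian
sequence with time-bandwidth product 1, computed from the standard
tridiagonal eigenproblem (no installed package provides DPSS sequences; the
implementation is cross-checked against independently computed reference
values in the tests). The 500 ms analysis windows give a 2 Hz grid, on
which every band edge (8, 12, 20, 34, 36, 66 Hz, and 32 Hz for the SSVEP)
falls exactly. Time-frequency spectrograms use 250 ms windows (4 Hz
resolution) stepped by 25 ms; at 500 Hz the step quantizes to 12 samples.
Change spectrograms divide by the mean power of windows lying fully inside
the baseline, and power is always averaged across repeats *before* any log
ratio - per-repeat dB values would carry the chi-squared log bias
(about -2.5 dB for a single window).

The 1/f character of the baseline is summarised by fitting
$P(f) = A f^{-\beta}$ over 56-84 Hz: a closed-form log-log regression
optionally refined by a Nelder-Mead simplex on the linear-domain squared
error. Inside the artifact cascade only the closed-form estimate is used -
the rejection rule needs only the sign of $\beta$, and the refinement adds
nothing to a sign decision at a measurable per-electrode cost.

## Artifact rejection

The cascade follows a fixed order. (1) Repeat-wise robust thresholding per
electrode: a repeat is flagged when its maximum absolute amplitude or mean
log PSD over -500-750 ms exceeds the median + 6 MAD of that electrode's
repeats (the thresholding statistic is our choice - the original thresholds
live in uncited prior work - and both multipliers are configurable);
electrodes flagged on more than 30% of repeats are discarded. (2) Repeats
flagged on more than 10% of the remaining electrodes are discarded.
(3) Electrodes with negative baseline PSD slope are discarded. (4) A block
survives only if, after propagating bad unipolar electrodes to the bipolar
montage, each of the three analysis-pair triads retains at least one clean
pair. Recording-time exclusions (e.g. high impedance) enter as an input
bad-electrode list. The cascade is single-pass, as the stage order is
printed; it is a fixed point at realistic artifact densities, but we note
that for pathological flag matrices near the 30% boundary a re-run on the
survivors could reject more (the property test asserts idempotence in the
realistic regime only).

## Eye analysis

Repeats containing blinks (NaN runs) or excursions beyond a 5 degree square
fixation window during -0.5-0.75 s are rejected before any EEG statistics.
Microsaccades are detected per blink-free segment with the classic
velocity-threshold method: velocities from a +/-2-sample weighted central
difference, per-axis robust SDs $\sigma = \sqrt{\langle v^2\rangle_{med} -
\langle v\rangle_{med}^2}$, an elliptic threshold at $\lambda = 6$ robust
SDs, a 10 ms minimum duration, and a 20 ms merge gap. These are the
originating method's canonical parameters, not values taken from the study
being emulated, and all are configurable. The main sequence (log peak
velocity vs log maximum displacement) and the event rate summarise detector
output; pupillary reactivity is the per-repeat coefficient of variation of
pupil diameter, averaged over analyzable repeats.

## The synthetic cohort generator

Raw cohort EEG is not desk-scale, so every stage is exercised against a
generator that produces the statistical structure the analysis assumes:

* **Background**: per-channel $1/f$ noise, $P(f) = A f^{-\beta}$ with
  $A = 200\ \mu V^2$/Hz at 1 Hz and $\beta = 1.8$, synthesized in the
  frequency domain (channels are random unit-norm mixtures of 16 latent
  series, which preserves each channel's spectrum while keeping generation
  a single FFT per trial).
* **Alpha**: band-limited (8-12 Hz) noise, 5 uV, suppressed to a power
  ratio of 0.4 from stimulus onset - equally in every group, making alpha a
  true negative control.
* **Gamma**: amplitude-gated band-pass Gaussian noise in 20-34 and
  36-66 Hz (4th-order Butterworth magnitude applied as a zero-phase
  spectral mask, the filtfilt-equivalent response), switched on 50 ms after
  onset and sustained through the stimulus. Amplitudes (6.5 and 5.5 uV for
  a unit-gain healthy subject) were chosen once so that control subjects
  show roughly a 4x stimulus/baseline band power ratio (~6 dB), the
  magnitude scale typical of strong induced-gamma responders; the study
  being emulated reports no effect size in dB, so these are free parameters
  of the generator, not reproduced values. Cases scale gamma amplitude by a
  deficit factor (0.6 for MCI, 0.5 for AD); subjects carry log-normal gain
  variability (SD 0.25), a mild age decline and a female-over-male factor.
* **Topography**: induced components follow a broad gain map peaked at Oz;
  evoked components (ERP, SSVEP) follow a steeper map, so that bipolar
  derivations - which cancel common-mode signal - retain them.
* **ERP**: a fixed three-lobed template (P1/N1/P2 at 100/170/230 ms) with
  group-independent amplitude, matching the finding that ERPs do not
  differ between groups.
* **SSVEP**: a 32 Hz sinusoid during counterphase (16 cps) stimuli only.
* **Eyes**: stationary low-pass Gaussian drift (0.15 degrees SD, ~1.4
  deg/s velocity noise) plus white tracker noise, ballistic minimum-jerk
  microsaccades (log-normal amplitudes, median 0.35 degrees, 18 ms) with a
  recentring bias, Poisson blinks encoded as NaN runs, occasional ramped
  excursions beyond the fixation window, and a pupil trace with a slow
  stimulus-locked constriction.
* **Artifacts**: with 2% per-repeat probability, a ~500 uV transient on
  one or two electrodes, or a flat- or rising-spectrum channel replacement
  that trips the slope rule.

One integer seed drives a hierarchical stream (cohort, subject, trial), so
any subset of the data regenerates identically. The generator emulates the
*statistical* structure only: there is no head model, no volume conduction
beyond the smooth gain maps, no line noise or EMG, and channel noise
correlations are random rather than distance-dependent. Passing tests
therefore show that the pipeline recovers known structure of this kind -
they do not certify performance on real recordings.

## Problem sizes and numerical choices

The generator's default sampling rate is 500 Hz (the analysis bands end at
84 Hz, far below Nyquist) and the default epoch spans -1.0-0.8 s. The
seeded replicate study (`run_replicate_study`) trims the epoch to
-0.52-0.8 s - the samples outside every analysis window - and uses two
conditions (2 and 4 cpd) with six repeats each per subject, analyzing only
the subjects each comparison needs (12 cases and their matched controls
from a 74-subject healthy pool); 100 seeds per arm then run in minutes
while preserving every pipeline stage. Reported per-band rejection rates
in that study use Kruskal-Wallis at $\alpha = 0.05$; bootstrap size is
reduced to 200 there because only the K-W decision enters the criterion,
while final reported comparisons use the full 10,000.

Other numerical choices: band sums include both edge bins; the SSVEP bin
must lie exactly on the grid (an error otherwise, rather than silent
interpolation); ERP peak windows are conventional visual-ERP defaults
(P1 75-125, N1 125-200, P2 175-300 ms) exposed in the call; degenerate
channels (NaN or flat-zero segments) are flagged wholesale; a case without
any analyzable matched control is dropped from the comparison (never
matched loosely), and comparisons require at least one surviving case.
Kruskal-Wallis degrees of freedom are the standard $k - 1$.

## Known limitations

* The packaged 112-pair scheme is a documented convention, not a
  reconstruction of the original montage's neighbour rule.
* Multi-block pooling is supported in principle but synthetic subjects are
  generated as one block; the block rule's interaction with real
  multi-block recordings is untested.
* The Bayes factor integrates the noncentral-t likelihood numerically;
  far outside $|t| \lesssim 20$ the noncentral-t density itself limits
  precision.
* No EDF/BIDS ingestion: cohorts live as in-memory containers with a
  plain-text metadata mirror and RDS persistence.
* Orientation selectivity is computed from supplied per-orientation powers;
  the generator's tuning is flat by design, so selectivity near zero is an
  assumption of the synthetic world, not a finding.
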
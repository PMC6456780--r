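---
title: "Simulating and analysing multifeature MMN studies with mmnkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing multifeature MMN studies with mmnkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnkit)
```

## The problem

The mismatch negativity (MMN) is a negative deflection of the auditory
event-related potential, peaking roughly 100--250 ms after a rare "deviant"
sound embedded in a train of repeated "standards". It indexes preattentive
auditory change detection, and group differences in its amplitude, latency
and area under the curve (AUC) are used to probe disorders of auditory
prediction such as tinnitus. `mmnkit` implements a complete, testable
pipeline for such studies:

1. **Paradigm generation** -- a multifeature oddball design in which every
   deviant is sandwiched between standards, with four deviant classes
   (frequency up / frequency down / shortened duration / silent gap);
2. **Synthetic EEG** -- a forward model producing multichannel recordings
   whose MMN parameters follow known per-group distributions, so that every
   downstream stage can be validated against ground truth;
3. **Preprocessing** -- band-pass filtering, ocular artifact removal,
   epoching, amplitude-based rejection;
4. **ERP analysis** -- per-condition averaging, deviant-minus-standard
   difference waves, a frontocentral region of interest (ROI), and the
   mastoid polarity-reversal validity check;
5. **Feature extraction** -- MMN amplitude, latency and AUC;
6. **Group statistics** -- one-way ANOVA with Tukey HSD across groups,
   repeated-measures ANOVA with Bonferroni-adjusted paired comparisons
   across deviant types, rank tests, and summary-statistic forms that
   operate on published means and SDs directly.

## The paradigm

The standard stimulus is the sum of three sinusoids at 7,500, 8,000 and
8,500 Hz, 75 ms long with 5 ms raised-cosine rise/fall ramps. Frequency
deviants rescale all three components by a factor of $1 \pm 0.10$, giving
8,250/8,800/9,350 Hz and 6,750/7,200/7,650 Hz; the duration deviant is
25 ms long (15 ms plateau); the gap deviant silences a central 7 ms window
whose edges carry 1 ms ramps. Each of the four blocks holds 91 trials: 10
warm-up standards, then a strict deviant--standard alternation starting
with a deviant, so no two standards are ever adjacent after the warm-up and
every deviant is preceded by a standard. That alternation fixes the realized
composition at 41 deviants and 50 standards per block (about 45% deviants);
a literal 50/50 split is arithmetically incompatible with 91 trials, a
10-standard warm-up and the alternation constraint, so the generator
enforces the structural constraints and reports realized counts. The
interstimulus interval is 900 ms offset-to-onset; with that reading the
4 x 91 schedule spans just under six minutes, which matches the intended
presentation time -- an onset-to-onset reading would not.

```{r paradigm}
cfg <- paradigm_config()
synthesize_stimulus("frequency_high", cfg)$frequencies_hz
ev <- generate_paradigm(cfg, seed = 1)
c(n_trials = nrow(ev), minutes = round(attr(ev, "total_span_s") / 60))
```

Design choices the stimulus description leaves open, resolved once here:
the three standard tones are *summed* into one complex (not interleaved as
separate standards); ramps are raised-cosine (configurable to linear) to
limit spectral splatter; audio is synthesized at 44.1 kHz; deviant classes
are mixed within every block and allocated in as-equal-as-possible counts,
which also splits the frequency deviants roughly half upward / half
downward.

## The forward model

Recordings are simulated at 1,024 Hz on 29 scalp sites of the 10-10 system
(including mastoids M1/M2) plus two EOG channels, nose-referenced, with a
1 s lead-in before the first stimulus. Every stimulus evokes fixed N1
(-2.5 uV, 100 ms, SD 15 ms) and P2 (+2 uV, 180 ms, SD 25 ms) components;
deviants additionally evoke an MMN. All evoked components are Gaussians in
time -- the waveform shape is not constrained by the measurement
conventions we implement, and Gaussians make every downstream check
available in closed form. The MMN width is fixed at SD 25 ms; its amplitude
and latency are per-subject, per-deviant-kind parameters.

Subject parameters are drawn from per-group Normal distributions whose
means and SDs are the package's reference values
(`default_group_parameters()`): for example, higher-frequency MMN amplitude
is -5.49 (SD 1.68) uV in controls, -6.64 (2.08) uV in compensated tinnitus
and -3.78 (1.55) uV in decompensated tinnitus. Amplitudes are clipped at
0 uV and latencies to [100, 250] ms. The tabulated SDs are treated as
between-subject SDs; trial-to-trial MMN variability is unreported in the
reference data and defaults to zero (a config knob).

The topography assigns gain 1.0 to the frontocentral ROI (F3, F4, Fz, FC3,
FC4, FCz, Cz), 0.5 to its immediate neighbours, 0.1 to distant sites and
-0.4 to the mastoids. The mastoid sign inversion is the property that
matters -- it produces the polarity reversal used as the MMN validity
criterion; the remaining gains are plausible but not fitted to any head
model (no lead-field simulation is attempted).

Background activity comprises: 1/f ("pink") noise, default 3.5 uV RMS per
channel -- a typical post-filter background for an ERP laboratory
recording; posterior-dominant 10 Hz alpha, default 2 uV RMS at its maximal
site; eye blinks as 300 ms raised-cosine transients at 12 per minute and
150 uV on the EOG channels, projected frontally onto the scalp; and
optional 50 Hz mains interference (off by default, since the emulated
acquisition chain notches it). What the generator does *not* emulate:
correlated inter-channel noise structure beyond the deterministic
topographies, non-stationary drowsiness/alpha bursts, muscle and cardiac
artifacts, electrode drift. Passing tests on this synthetic data therefore
validate the *measurement pipeline*, not robustness to every artifact class
found in real recordings.

## Preprocessing

Filtering is a zero-phase 4th-order Butterworth band-pass, 1--20 Hz. The
default realization applies the squared Butterworth magnitude in the
frequency domain (one FFT per recording, padded to a fast length), which is
the stationary response of the forward--backward cascade; a per-channel
`signal::filtfilt()` path is available and the two agree away from the
recording edges.

Ocular artifacts are removed either by ICA (symmetric FastICA, tanh
contrast, run over scalp + EOG channels) with automatic component
selection -- any component whose absolute correlation with an EOG channel
exceeds 0.7 is removed, replacing visual inspection with a reproducible
rule -- or by least-squares regression of the EOG channels out of the
scalp. Regression is exact for the simulated blink model (blinks project
instantaneously to EOG) and is the default in the batch pipeline for
speed; ICA is validated separately. A caveat worth knowing: with sparse
blinks and short recordings, finite-sample correlation between the blink
source and the ERP lets a few percent of ERP variance leak into the
removed component, so ICA-based removal is most accurate on full-length
recordings.

Epochs span -50 to +900 ms around each onset; the mean of the prestimulus
interval is subtracted per channel. Trials whose absolute amplitude exceeds
50 uV on any scalp channel (EOG excluded -- it is not a scalp site; and
read as absolute post-baseline amplitude, not peak-to-peak) are rejected;
rejection is applied after ocular correction, since the order is otherwise
ambiguous and correction-first preserves more trials. The 10 warm-up
standards of each block are excluded from averaging. Trials too close to a
recording edge are flagged rather than silently dropped.

## Features

Difference waves are deviant evoked minus standard evoked, channel-wise.
Features are measured on the unweighted ROI mean trace (computed before
peak picking; the per-electrode-then-average alternative is exposed by the
`roi` argument but the ROI-average-first convention is the default, since
averaging first is the common reading of "calculated over these sites").

* **Amplitude/latency**: the most negative sample of the ROI trace in
  100--250 ms; ties break to the earliest time; latency is reported at
  sample resolution (under 1 ms at 1,024 Hz, so no interpolation).
* **Reference level**: the "nearest extremum" convention is implemented as
  the local maximum nearest in time to the peak, searched on both sides
  with the preceding side preferred on ties, falling back to the 0 uV
  prestimulus baseline when the trace has no interior maximum. Amplitude is
  reported relative to this level, signed (negative).
* **AUC**: the integral of (reference - wave) over the maximal interval
  around the peak on which the wave stays below the reference, bounded by
  linearly interpolated reference crossings or the epoch edges;
  trapezoidal rule, in uV*ms.
* **Validity**: the polarity-reversal check compares the sign of the mean
  of M1 and M2 at the ROI-peak latency against the ROI value there (a
  window-mean variant is available).

One documented tension in the reference results: the results prose calls
decompensated MMNs "larger" while the tabulated means, the abstract and the
figures all show decompensated amplitudes *less negative* (smaller MMN).
The package follows the tabulated values; comparisons of "size" in the
documentation always mean |amplitude|.

## Statistics

`run_study()` applies, per feature and deviant kind, a one-way
fixed-effects ANOVA across groups plus Tukey HSD; and per group and
feature, a one-factor repeated-measures ANOVA across the four deviant
kinds (F = MS_condition / MS_condition-x-subject, df (c-1), (c-1)(n-1),
uncorrected by default -- matching the F(3, 57) layout for n = 20 --
with Greenhouse-Geisser behind a flag) plus Bonferroni-adjusted paired t
tests. Mann-Whitney U (tie-corrected, exact for small tie-free samples)
and pooled-variance t tests cover two-group comparisons. No correction is
applied across the twelve between-group ANOVAs, matching the reference
analysis plan; p values are reported in full precision and printed to four
decimals.

The summary-statistic forms, `anova_from_summary()` and `t_from_summary()`,
recompute F and t from printed group means/SDs/sizes. On the demographic
table this reproduces every printed statistic to its printed precision
(e.g. age F = 0.71 vs printed 0.70; THI t = -18.71 vs printed -18.70). On
the MMN feature table the recomputed F values run ~3--4% below the printed
ones (13.01 vs 13.41 for higher-frequency amplitude); the discrepancy is
consistent with the printed moments themselves being rounded to two
decimals, and is documented rather than resolved. The pooled (Student)
form of the t test is used because it is the form that reproduces the
printed demographic t values.

## Numerical choices and degenerate inputs

* All randomness flows from integer seeds; cohort, paradigm and
  per-subject noise seeds are derived from one root seed.
* FFT lengths are padded to 5-smooth integers (R's mixed-radix FFT is
  quadratic on large prime factors).
* A repeated-measures matrix with no condition variance returns F = 0,
  p = 1 rather than 0/0; paired comparisons with zero-variance differences
  return p = 1 (mean difference 0) or p = 0 (constant nonzero difference).
* An all-trials-rejected epoch set is an explicit error advising threshold
  review; a condition with zero kept trials is an explicit error naming
  the condition; a missing deviant kind yields NA features, never
  fabricated values.
* ICA falls back to EOG regression with a warning if the decomposition
  fails; a silent EOG channel means "nothing ocular to remove".

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles
(brute-force scans, closed forms, sum-of-squares decompositions) and the
whole pipeline against simulation ground truth: noise-free cohorts must
return the injected amplitudes within the tolerance set by filter ringing
(10%), and a 20-per-group cohort simulated at the default noise level must
reproduce the injected group ordering and means within sampling error, with
the between-group ANOVA rejecting at alpha = 0.01. Type-I calibration of
the one-way ANOVA uses 5,000 summary-level replicates (a full-EEG version
would add nothing: the test consumes feature tables). The parameter
recovery run uses the full 4 x 91-trial paradigm per subject -- about six
minutes of simulated EEG each -- which we consider the smallest problem
size that exercises the pipeline under its intended conditions.

## Limitations

* The forward model is phenomenological: fixed topography vectors, not a
  volume-conductor model; no source-space claims can be tested with it.
* Between-subject latency SDs are applied as such; if the reference values
  partly reflect measurement noise, simulated cohorts are somewhat more
  variable in latency than real ones.
* The peak-based amplitude measure carries the usual noise-dependent
  magnitude inflation of extremum statistics; group comparisons remain
  valid because the bias is shared, but absolute amplitudes from noisy
  data should be read with that in mind.
* `reversal_ok` uses the instantaneous mastoid value at one latency; on
  low-SNR single subjects a window-mean check (`mode = "mean"`) is more
  stable.
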
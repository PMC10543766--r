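---
title: "Speech-brain coherence in infant EEG: model, pipeline and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speech-brain coherence in infant EEG: model, pipeline and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Infants' cortical activity tracks the slow amplitude modulations of speech.
In infant-directed speech those modulations concentrate at two rhythms: the
stressed-syllable rate (analysed here as 1-1.75 Hz) and the syllable rate
(2.5-3.5 Hz). `sbcoh` quantifies this tracking with speech-brain coherence
(SBC): for the speech envelope $x$ and an EEG channel $y$,

$$\mathrm{coh}_{xy}(\omega) \;=\;
  \frac{\lvert S_{xy}(\omega)\rvert}{\sqrt{S_{xx}(\omega)\,S_{yy}(\omega)}},$$

where $S_{xy}$ is the cross-spectral density averaged over 4-second epochs
and $S_{xx}$, $S_{yy}$ the corresponding auto-spectra. SBC lies in $[0,1]$
and measures the consistency of the phase difference between envelope and
EEG at frequency $\omega$, independently of amplitude.

Because the true infant data behind this design are not publicly deposited,
the package pairs the analysis chain with a synthetic-data generator with
known ground truth. Every stage is then validated by parameter recovery:
effects the generator injects must be found, effects it withholds must not.

## The pipeline

1. **Envelope** — magnitude of the analytic (Hilbert) signal, smoothed with
   a zero-phase second-order Butterworth low-pass and resampled to the EEG
   rate (500 Hz). Envelope-tracking pipelines vary in where they place the
   smoothing filter and at what cutoff; we place it after rectification
   with a default cutoff of 30 Hz, matching the EEG band, and expose both
   choices (`extract_envelope()`). Resampling is Fourier-domain (brick-wall
   anti-aliasing, amplitude preserving); the `signal` package's polyphase
   resampler was rejected after it showed a ~15% passband gain error on a
   constant input.
2. **EEG preprocessing** — 0.1 Hz high-pass (order 2, i.e. a -12 dB/oct
   roll-off) and 30 Hz low-pass, both zero-phase. The low-pass
   order is a free choice; order 4 is used so that a 50 Hz
   mains tone is attenuated below 10% RMS after the forward-backward pass
   (order 2 would leave ~11.5%). Blocks are cut into 4-s epochs on a 1-s
   sliding grid (an 18.9 s block yields 15 epochs); epochs with less than
   25% screen-looking (strictly less than 1 s of 4 s) are excluded, as are
   epochs in which any EEG channel strictly exceeds 150 uV in magnitude
   (boundary samples survive both rules). Artifact components with known
   topographies are removed by projection onto their orthogonal complement;
   declared bad channels are repaired by spherical-spline interpolation
   (order m = 4, 20 Legendre terms); data are re-referenced to the (linked)
   mastoids and demeaned. A subject enters the group analysis only with at
   least 30 kept epochs per gaze condition.
3. **Coherence and surrogates** — Hanning-tapered DFTs at 1-10 Hz in
   0.25 Hz steps (the resolution of a 4-s window), coherence across kept
   epochs, and an envelope-shuffling surrogate distribution (100
   permutations) whose mean and SD standardise the observed coherence into
   z-scores. Band scalars average the z over the stress bins (1.00-1.75,
   four bins) and syllable bins (2.50-3.50, five bins), then over channels,
   giving one value per band per infant.
4. **Statistics** — nonparametric cluster-based permutation tests over
   electrodes (x frequencies) with within-subject sign-flips, 1000
   permutations escalating to 10000 when the smallest p falls in
   [0.03, 0.10]; absolute theta power (3-6 Hz, 13 bins) compared between
   gaze conditions; a paired t-test on mean looking times; and OLS models
   of 18-month vocabulary on the band z-scores and 10-month vocabulary,
   with VIFs and a non-constant-variance score test that decides a
   square-root transform of the expressive outcome.

## The surrogate null and overlapping epochs

The surrogate scheme destroys envelope-EEG alignment by shuffling envelope
epochs against EEG epochs. With a 1-s sliding grid, however, neighbouring
epochs share 75% of their samples, and the aligned cross-spectral products
of overlapping windows are strongly correlated (a 1-s shift rotates the
phases of envelope and EEG coefficients equally, leaving their product
unchanged). A *free* epoch shuffle breaks exactly this dependence, so its
coherence is biased low relative to the aligned estimate even under zero
coupling: in our null simulations the subject band z-scores averaged about
+0.75 under the free shuffle.

The default surrogate therefore permutes the envelope at the *block* level:
whole envelope blocks are reassigned to EEG blocks with the within-block
window order preserved. Alignment is still destroyed (envelopes of
different blocks are independent), but the sliding-window dependence is
identical in observed and surrogate data. Under this scheme the null mean
of the subject band z is indistinguishable from 0 (see
`study_null_calibration()`). The free shuffle remains available
(`surrogate_distribution(..., unit = "epoch")`) and is what the
exhaustive-enumeration unit test uses; analyses that combine overlapping
epochs with free epoch shuffles should expect inflated
observed-vs-surrogate effects.

A related consequence of averaging: the per-cell (channel x bin) z-scores
have SD near 1 under the null, but the per-subject band summary averages
~20-100 correlated cells, so its between-subject SD is well below 1 (~0.3
on the full montage, ~0.5 on the reduced study montage). Cell-level scale,
not summary-level scale, is the calibration property the tests assert.

## Two-sided cluster p-values

The permutation null records, for each sign-flip assignment, the maximum
*absolute* cluster mass over both signs. Comparing an observed cluster's
absolute mass against this null is already a two-sided, familywise-error-
controlling test; doubling the resulting p (as is sometimes done with
single-sided maxima) double-counts sign and made the empirical familywise
error rate 0.01 instead of 0.05 in our 200-cohort null study. The package
therefore reports `p = (#{null maxima >= |mass|} + 1) / (n_perm + 1)`
without doubling; with it the measured rate is consistent with the nominal
0.05.

## What the generator emulates

* **Envelopes.** Sentence trains (normal durations, mean 3.197 s, SD
  0.507 s, truncated at 0.5 s; 1.5 s inter-sentence intervals; 18.9 s
  blocks) carrying two multiplicative quasi-periodic raised-cosine
  modulators whose cycle rates are redrawn uniformly per cycle from
  0.87-1.72 Hz (stress) and 2.62-3.57 Hz (syllables). Modulation
  depth is a free parameter; the default 0.5 makes both spectral
  peaks clearly detectable while keeping the envelope positive.
* **EEG.** Each channel sums band-limited, phase-delayed envelope copies
  (per-channel gains, optionally different between gaze conditions), an
  optional condition-scalable oscillatory background, `1/f` noise, and
  blink/movement artifacts. The noise is 70% spatially shared across
  channels (volume-conduction-like) and amplitude-modulated by a slow
  (~10 s) log-normal process emulating arousal-state nonstationarity —
  both features visible in real infant EEG and necessary for realistic
  between-subject dispersion of the band z-scores. Default coupling gains
  (1.1 uV stress, 0.7 uV syllable per unit envelope) were chosen once so
  that the default cohort's band z-scores land near the magnitudes reported
  for real ten-month-olds (means ~1.7 and ~1.5); phase lags correspond to
  a ~100 ms neural delay at each band centre. Band-limiting of the
  envelope copies uses frequency-domain masks with raised-cosine edges —
  IIR designs are numerically unstable at 1-3.5 Hz on a 500 Hz rate.
* **Looking.** Per block, a long-run looking proportion is drawn from a
  Beta distribution (default mean 0.9, matching mean looking of ~3.6 s per
  4-s epoch); screen/away intervals alternate with exponential durations
  whose means realise that proportion, quantised to 40 ms video frames.
* **Vocabulary.** Ten-month receptive/expressive proportions are Beta with
  means/SDs 0.26/0.18 and 0.02/0.03. Eighteen-month outcomes follow the
  generating regressions: the square-rooted expressive proportion has
  intercept 0.20, syllable-rate coefficient 0.09, stress-rate coefficient
  0.00 and baseline coefficient 2.75; the receptive proportion has
  intercept 0.43 and baseline coefficient 0.62. Noise SDs (0.08 and 0.12)
  give fits of roughly the published explanatory strength.

The generator does **not** emulate: real speech acoustics (the envelope is
synthesised directly), gaze-contingent neural effects (the default design
treats gaze as neurally neutral; condition differences are injected
explicitly when wanted), volume conduction from modelled sources, age-varying spectra, or channel-specific artifact mixtures beyond
the blink/movement templates. Passing tests therefore demonstrate that the
pipeline measures what the forward model injects — not that real infant
EEG satisfies the forward model.

## Numerical and design choices

* Epoch windows are half-open `[start, start + 4 s)` with 0-based sample
  indexing; window starts are whole seconds from block onset.
* "Exceeding" thresholds are strict inequalities at both 150 uV (EEG) and
  250 uV (EOG); boundary samples are kept. EOG screening operates on 1-s
  continuous segments (`flag_bad_segments()`); whether whole epochs or
  segments should be dropped is not specified upstream, so overlapping
  epochs are marked, and logged as such.
* The Hanning taper is the default for both coherence and power (boxcar
  available); surrogate permutations are drawn uniformly with replacement
  from the permutation group, identity allowed — with 100 draws its effect
  is negligible.
* Cluster-forming threshold: two-tailed t at alpha = 0.05 with
  `df = n_subjects - 1`; cluster statistic: sum of member t values;
  spatial adjacency from the 0.25 quantile of template inter-electrode
  distances (median 6 neighbours on the 23-channel montage, connected);
  frequency adjacency (same electrode, neighbouring bin) is on by default
  for multi-bin tests.
* Zero-variance cells clamp t to sign x 1e6; zero-power bins define
  coherence 0; zero surrogate SD drops the bin from band averages. All
  are logged paths, not errors.
* ICA estimation is out of scope: component removal takes known
  topographies (from the generator's mixing or supplied externally), so
  the coherence-specific machinery stays independent of any particular
  component-decomposition algorithm.
* RNG: one root seed, per-subject child streams derived by an integer
  hash (`child_seed()`), recorded in the run manifest; identical
  config + seed reproduces byte-identical files.

## Validation studies and their problem sizes

The package ships its validation experiments as functions so that tests
and the acceptance script rerun them from scratch:

* `study_null_calibration()` — 50 coupling-free cohorts of 4 subjects on a
  7-channel montage, 4 blocks of 10 s per condition (28 epochs/condition),
  100 surrogate permutations: grand mean of subject band z within 0.2 of 0.
* `study_cluster_fpr()` — 200 null cohorts of 10 subjects, identical
  coupling in both gaze conditions, 200 cluster permutations: familywise
  false-positive rate of the direct-vs-averted syllable test inside the
  95% binomial band around 0.05. Ten subjects make the sign-flip group
  (2^10 assignments) large relative to the permutation count; with fewer
  subjects the ties with the global-flip symmetry make the test visibly
  discrete and conservative.
* `study_detection()` — 20 cohorts of 20 subjects with syllable-band
  coupling gain 3 uV: the observed-vs-surrogate band test detects a
  positive cluster in >= 90% of cohorts.
* `study_theta_detection()` — frontal 3-6 Hz background at 8 uV RMS under
  direct vs 4 uV under averted gaze: a significant positive frontal
  cluster in >= 80% of 20 cohorts.
* `study_vocab_recovery()` — OLS refits of the generating expressive model
  at n = 200: mean syllable coefficient within 0.02 of 0.09 over 100
  replicates; 95% CI coverage between 93% and 97% over 500 fits.

These cohort sizes are deliberate scale-downs of the full design (50
subjects, 30 blocks x 18.9 s per condition, 23 channels): the reduced
montage and block counts keep whole-cohort Monte-Carlo studies cheap while
preserving every structural feature the statistics rely on (sliding-window
overlap, block structure, per-condition surrogates). The Monte-Carlo
studies also skip the 0.1-30 Hz filter stage: zero-phase filtering rescales
every epoch identically per frequency bin, and coherence, z-scores and
paired t-maps are exactly invariant to such a rescaling, so the omission
changes nothing but runtime (single-subject tests keep the filter on).

## Known limitations

* The analysis inherits the estimator's epoch-exchangeability assumption;
  serial dependence beyond the block structure (e.g. drifting attention
  within blocks) is not modelled by the surrogate.
* Coherence of overlapping epochs with block-level surrogates is
  calibrated in mean, but the effective degrees of freedom are fewer than
  the epoch count suggests; per-subject SEs are not reported for that
  reason (inference is by permutation).
* The spherical-spline repair assumes a spherical head and template
  positions; repairs of more than ~3 channels on 23 are extrapolations.
* The vocabulary model is linear-Gaussian on a square-root scale with
  clipping to [0, 1]; heavy clipping (strong effects plus large noise)
  would bias recovery, which the defaults avoid.
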
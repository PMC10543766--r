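# sbcoh — speech–brain coherence analysis of infant EEG

`sbcoh` implements a complete analysis chain for studies of infants'
cortical tracking of naturalistic speech, together with a synthetic-data
generator with known ground truth so that every stage can be validated by
parameter recovery.

The scientific question it serves: does a ten-month-old's EEG follow the
slow amplitude modulations of infant-directed speech — the
stressed-syllable rhythm (1–1.75 Hz) and the syllable rhythm (2.5–3.5 Hz) —
does that tracking differ when the speaker addresses the infant with direct
versus averted eye gaze, and does it predict vocabulary eight months later?

At its core is speech–brain coherence (SBC) between the speech amplitude
envelope *x* and each EEG channel *y*:

```
coh_xy(ω) = |S_xy(ω)| / sqrt(S_xx(ω) · S_yy(ω))
```

with cross- and auto-spectral densities averaged over 4-second epochs cut
on a 1-second sliding grid (0.25 Hz resolution, 1–10 Hz). Observed
coherence is standardised against an envelope-shuffling surrogate
distribution, band-averaged, and taken to group level with nonparametric
cluster-based permutation tests over electrodes × frequencies; attention is
checked via looking times and absolute theta power (3–6 Hz); band z-scores
enter OLS models of later vocabulary with collinearity and
heteroscedasticity diagnostics.

## What is in the package

| Stage | Functions |
|---|---|
| Synthetic cohorts | `sim_config()`, `synth_envelope()`, `synth_recording()`, `synth_looking()`, `synth_vocab()`, `simulate_subject()` |
| Envelope | `extract_envelope()`, `epoch_envelope()`, `resample_fft()` |
| EEG preprocessing | `bandpass()`, `segment()`, `add_looking()`, `gate_epochs()`, `reject_amplitude()`, `remove_components()`, `interpolate_channels()`, `rereference()`, `include_subject()` |
| Coherence | `fft_epochs()`, `compute_coherence()`, `surrogate_distribution()`, `zscore_coherence()` |
| Cluster statistics | `build_adjacency()`, `paired_tmap()`, `find_clusters()`, `permutation_test()` |
| Attention | `power_spectra()`, `theta_contrast()`, `looking_ttest()` |
| Vocabulary | `proportion_scores()`, `fit_linear()`, `ncv_test()`, `vif()`, `run_vocab_models()` |
| Orchestration | `process_subject()`, `group_analysis()`, `run_simulation()`, `run_analysis()` |
| Validation studies | `study_null_calibration()`, `study_cluster_fpr()`, `study_detection()`, `study_theta_detection()`, `study_vocab_recovery()` |

File formats: BrainVision (`.vhdr/.vmrk/.eeg`) for EEG, float WAV for
envelopes/audio, TSV for frame-coded looking records, CSV for CDI
vocabulary scores, YAML for configurations, JSON for results and the run
manifest. A thin command-line wrapper lives at
`inst/scripts/sbcoh-pipeline.R` (verbs `simulate`, `analyse`, `all`).

## Worked example

Simulate a small coupled cohort, run the full analysis, and look at the
group results:

```r
library(sbcoh)

cfg <- sim_config(
  n_subjects = 10,
  n_blocks_per_condition = 4,
  block_duration_s = 10,
  channel_labels = c("Fp1", "F3", "Fz", "F4", "C3", "Cz", "C4"),
  coupling = detection_coupling(3),   # syllable-band coupling, 3 uV
  artifact_spec = list(blink_rate_per_min = 0, blink_amplitude_uv = 0,
                       movement_rate_per_min = 0, movement_amplitude_uv = 0),
  seed = 5)

run_simulation(cfg, "cohort")                      # writes BrainVision + WAV + TSV + CSV
summary <- run_analysis("cohort", "report",
                        n_perm = 200, min_per_condition = 10)
str(summary$cluster_p)
#> List of 6
#>  $ overall      : num 0.0199
#>  $ stress       : num 1
#>  $ syllable     : num 0.0149
#>  $ gaze_stress  : num 1
#>  $ gaze_syllable: num 1
#>  $ theta        : num 1
```

Reading the numbers: the observed-vs-surrogate tests find the injected
syllable-band coupling (`syllable` p = 0.0149 and `overall` p = 0.0199 at
200 permutations) and correctly find nothing at the stress rate, no
direct-vs-averted difference (none was injected), and no theta-power
difference. `report/` additionally contains the per-epoch
report, per-subject coherence tables, band z-scores, the cluster JSON and
the two vocabulary regression tables.

The ground truth behind any simulated subject is available directly:

```r
sub <- simulate_subject(cfg, 1)
sub$ground_truth$gains
#>           Fp1 F3 Fz F4 C3 Cz C4
#> 2.5-3.5Hz   3  3  3  3  3  3  3
```

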
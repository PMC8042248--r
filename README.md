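# scalpHFO

Automated ripple-band high-frequency-oscillation (HFO) analysis for scalp
EEG in paediatric epilepsy.

HFOs — brief 80–250 Hz oscillatory events lasting tens of milliseconds —
are a promising non-invasive biomarker of epileptogenicity, but in
children their rates and characteristics change with age. `scalpHFO`
provides the full analysis chain for whole-night 10–20 scalp EEG:

* **Montage & selection** — EDF/BIDS-style reading, the 52-derivation
  bipolar neighbour montage of the 10–20 system, and selection of
  artifact-free 5-min N3 intervals from the first 3 h of sleep.
* **Detection** — a three-stage automated ripple detector: Stage I marks
  events of interest where the Hilbert envelope of the 80–250 Hz band-passed
  signal exceeds a baseline threshold determined in time windows of high
  Stockwell entropy (low oscillatory activity); Stage II requires a
  high-frequency peak isolated from low-frequency activity in the
  time–frequency plane; Stage III applies the scalp-specific rules —
  reject events with amplitude ≥ 40 µV, SNR < 4, or time-overlapping
  partners on the homologous contralateral channel.
* **Characterization** — per-channel rates (events / analyzed minutes),
  event frequency (crest-to-crest), duration (envelope above threshold),
  peak-to-peak amplitude, SNR against 0.5-s flanks, and ripple-band
  activity (RBA, mean in-band RMS on the highest-rate channel).
* **Reliability** — test–retest reliability of the HFO spatial profile:
  pairwise concordance of the highest-rate channel across 5- or 10-min
  blocks.
* **Cohort statistics** — median/iqr summaries, Wilcoxon comparisons,
  Spearman correlations of HFO features with age, and the OLS model
  `rate ~ CSWS + age group + log10(seizures/month) + RBA`, together with a
  packaged 30-patient per-patient summary table.
* **Simulation** — a synthetic EEG generator (1/f background with
  slow-wave and spindle components, injected Tukey-windowed ripples,
  high-amplitude and bilateral decoys, cohort-level age trends) so every
  stage is testable end to end with known ground truth.

## Worked example

Simulate a 5-min four-channel recording with ten injected 15-µV ripples,
detect, and compare against ground truth:

```r
library(scalpHFO)

cfg <- sim_config(labels = c("F3-C3", "F4-C4", "P3-O1", "P4-O2"),
                  duration_s = 300, seed = 5)
bg  <- generate_background(cfg)
set.seed(11)
truth <- random_events(cfg$labels, 300, n_ripple = 10,
                       ripple_amplitude_uv = 15)
inj    <- inject_events(bg, truth)
events <- detect_hfo(inj$recording)
head(events[events$status == "accepted", ], 4)
#>   channel onset_s duration_ms frequency_hz amplitude_uv   snr
#> 1   F3-C3   123.2        29.3          114         19.8 16.83
#> 2   F3-C3   287.1        33.2          114         13.3  7.99
#> 3   F4-C4    67.2        23.4          171         15.6 13.55
#> 4   F4-C4   119.3        24.4          137         16.9 13.38

match_events(events, inj$truth)[c("recall", "precision")]
#> $recall    [1] 0.9
#> $precision [1] 1
```

Nine of the ten injected ripples are recovered with no false positives;
measured frequencies, durations and amplitudes sit within a few Hz/ms/µV
of the injected parameters (the envelope-above-threshold duration is
slightly shorter than the full tapered support, by construction).

Recompute the cohort statistics from the packaged per-patient table:

```r
st <- reproduce_paper_stats()
st$total_minutes                 #> 1055 analyzed minutes
st$rate_younger$median           #> 2.4 HFO/min (< 7 years, n = 16)
st$rate_older$median             #> 0.65 HFO/min (>= 7 years, n = 14)
st$rate_age_group_p              #> 0.027 (rank-sum)
st$spearman_age_frequency$r      #> -0.576: HFO frequency falls with age
st$reliability_10min$median      #> 100 (% concordance, 10-min blocks)

fit_rate_model(load_cohort_table())$coefficients
#>               term estimate ci_low ci_high       p
#> 1        intercept     2.31 -1.408   6.030 2.1e-01
#> 2         csws_yes     6.54  4.297   8.787 2.9e-06
#> 3  age_group_older    -1.45 -2.844  -0.052 4.3e-02
#> 4 log_seizure_freq     0.32 -0.092   0.723 1.2e-01
#> 5              rba    -0.46 -2.807   1.885 6.9e-01
```

Patients with continuous spike-and-wave during sleep carry ~6.5 HFO/min
more than others, and the older age group ~1.5 HFO/min fewer, after
adjusting for seizure frequency and background ripple-band activity.

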
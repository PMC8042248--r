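---
title: "Ripple-band HFO analysis in scalp EEG: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ripple-band HFO analysis in scalp EEG: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalpHFO)
```

## The problem

High-frequency oscillations (HFO) — brief oscillatory EEG events in the
ripple band, 80–250 Hz, lasting tens of milliseconds — are a candidate
non-invasive biomarker of epileptogenicity. In children their rates and
characteristics change with brain maturation, so any clinical use must
account for age. `scalpHFO` implements a complete analysis chain for
whole-night scalp EEG recorded with the international 10–20 system:
automated three-stage ripple detection on a bipolar neighbour montage,
per-event and per-patient characterization (rate, frequency, duration,
amplitude, SNR, ripple-band activity), test–retest reliability of the HFO
spatial profile, and the cohort statistics that relate HFO features to age.
A synthetic EEG generator with known injected events makes every stage
testable without access to clinical recordings.

## Data selection and montage

Analysis is restricted to N3 sleep within the first 3 h after sleep onset,
where HFO rates are highest and muscle artifact lowest. Sleep onset is
taken as the start of the first scored non-wake epoch — the simplest
defensible reading when only a hypnogram is available. Scored N3 spans are
clipped to that window, annotated artifact spans are excised (splitting the
span), and each artifact-free span is tiled independently from its start
into 300-s intervals; residuals shorter than 300 s are discarded. Patients
contribute `5 × (number of intervals)` analyzed minutes to all rate
denominators. Two intervals is the hard floor for analysis and
`select_intervals()` warns below three, mirroring the cohort inclusion
practice.

The bipolar montage uses all pairs of neighbouring electrodes of the
19 montaged 10–20 positions (A1/A2 are recorded but have no montage
neighbours). The published constraint is only the total — 52 derivations —
so the shipped adjacency (`inst/extdata/bipolar_adjacency_1020.tsv`)
combines longitudinal and transverse nearest neighbours, the inter-row
diagonals of the frontal/central/parietal grid, and the
frontopolar/occipital midline diagonals: 14 + 18 + 16 + 4 = 52 pairs. The
table is itself under test: it must contain every derivation name that
appears in the published per-patient summaries and must be closed under
the left–right mirror map. Midline-only pairs (`Fz-Cz`, `Cz-Pz`) and
cross-midline pairs (`Fp1-Fp2`, `O1-O2`) are their own mirror images and
therefore have no partner on which a bilateral co-occurrence could be
observed; they are exempt from bilateral rejection by construction.
Derivation names are accepted in either electrode order and canonicalized
against the shipped table.

## The three-stage detector

**Stage I — entropy-baseline thresholding.** The channel is band-passed to
80–250 Hz (6th-order Butterworth, applied forward–backward for zero phase;
gain at 100 Hz within 0.5%, out-of-band attenuation far beyond 40 dB) and
its Hilbert envelope computed as the modulus of the analytic signal. The
record is scanned in 1-s windows; each window's Stockwell (S-) transform
power, averaged over time and restricted to the ripple band, is normalized
into a spectrum whose Shannon entropy measures flatness. Windows at or
above the 0.75 entropy quantile — the least oscillatory quarter — form the
baseline. The detection threshold is the median over baseline windows of
the per-window envelope maximum (multiplier 1.0). The per-window maximum
of near-Rayleigh noise is a stable high quantile of the envelope
distribution, and the median across windows resists contamination by
residual oscillatory windows; an early variant using the global baseline
maximum proved too conservative for short low-frequency ripples, whose
above-threshold runs then failed the oscillation count by construction.
Maximal runs of envelope above threshold are merged when closer than
10 ms, and kept as events of interest when at least 20 ms long (about four
cycles at 200 Hz) with at least 4 rectified-signal peaks above half the
threshold.

**Stage II — isolated peak in time–frequency space.** For each event the
S-transform power profile (4–250 Hz in 4-Hz steps, time-averaged over the
event, with 0.25 s context) must show a ripple-band peak separated from the
low-frequency (<40 Hz) maximum by a spectral trough no deeper than half the
ripple peak power (`stage2_trough_ratio = 0.5`, boundary inclusive).
Filtered spikes — band-limited transients with monotonically decaying
spectra — exhibit no trough and are rejected.

**Stage III — scalp-specific rejection.** The published criteria are
applied with their printed boundary semantics: amplitude ≥ 40 µV rejects
(40.0 rejects, 39.9 passes), SNR < 4 rejects (4.0 passes), and an event
co-occurring with any candidate on the homologous contralateral channel —
partial overlap in time, i.e. at least one shared sample on half-open
spans; touching boundaries do not overlap — rejects both partners.
Amplitude for the 40 µV rule is the same band-passed peak-to-peak used for
characterization, and the SNR is the same flank-ratio statistic, keeping a
single definition of each. Stages run in I→II→III order (recorded in the
configuration); the bilateral check considers all Stage-I candidates, so a
mirrored artifact rejected by Stage II on one side still vetoes its
partner. Events too close to an interval edge for at least 0.25 s of SNR
flank are dropped with the distinct status `rejected_edge`.

The Stage I/II constants above are free parameters of this implementation
(the published description fixes only the band, the 40 µV ceiling, the SNR
floor and the overlap rule); they live in `detector_config()` with these
defaults and carry no acceptance claims.

## Event and patient features

* **Rate**: accepted events per channel divided by analyzed minutes; by
  construction `rate × minutes` is the integer event count.
* **Frequency**: reciprocal of the mean crest-to-crest interval of the
  band-passed trace (crests = local maxima above zero), honouring the
  crest-and-trough definition; clipped to 80–250 Hz. An FFT-peak variant
  is available behind `method = "fft"` for sensitivity analysis.
* **Duration**: time the Hilbert envelope stays above the detection
  threshold — the defining run of the event. Note this is intrinsically
  shorter than the full support of a tapered oscillation; on
  Tukey(0.5)-windowed synthetic ripples the bias is a few ms at high
  amplitude and grows as the peak envelope approaches the threshold.
* **Amplitude**: largest absolute difference between adjacent extrema of
  the band-passed trace (highest peak-to-peak swing).
* **SNR**: mean band-passed power within the event divided by the mean
  power of the concatenated 0.5-s flanks; silent flanks yield an
  infinite-SNR sentinel with a warning.
* **RBA** (ripple-band activity): mean over intervals of the per-interval
  RMS of the band-passed signal on the highest-rate channel — a
  background-noise measure; an in-band sinusoid of amplitude A gives
  A/√2.

Patient summaries report the channel with the highest rate (ties broken by
event count, then lexicographic name), the morphology means over that
channel's accepted events, and RBA there. Morphology fields are populated
only for patients with more than 3 accepted HFOs.

## Test–retest reliability

The reliability of the HFO spatial profile is the percentage of unordered
block pairs whose "HFO area" — the single highest-rate channel of the
block — agrees, with the empty-block sentinel agreeing only with itself.
This pairwise-concordance reading is the simplest consistent with the
attainable published values (0, 100 and intermediate percentages); the
formula is isolated in `test_retest_reliability()` so alternative
definitions (top-k overlap, profile rank correlation) can be swapped in.
Blocks are consecutive non-overlapping groups of 5-min intervals with the
trailing remainder dropped; 10-min reliability requires more than 20 min
of data, 5-min reliability uses every interval and every patient.

## Cohort statistics

Distributions are summarized as median and interquartile range (type-7
quantiles). Group comparisons use Wilcoxon rank-sum / signed-rank tests
(normal approximation with continuity and tie corrections — with tied,
rounded table data exact p-values are unavailable, so published p-values
are treated as bounds, not equality targets). Correlations use
tie-corrected Spearman rank correlation with a t-approximation p-value.
The HFO rate model is ordinary least squares of the per-patient rate on an
intercept, a CSWS indicator, an older-age indicator (age ≥ 7 years), the
base-10 logarithm of monthly seizure frequency, and RBA. Base 10 was
chosen empirically: it reproduces the published coefficient table to its
printed precision, settling the ambiguity of an unspecified logarithm
(base e remains available via `log_base`).

`reproduce_paper_stats()` recomputes the cohort analysis from the packaged
per-patient table. Two reconstruction choices matter. First, the
characterization statistics (frequency, duration, amplitude, SNR, RBA
medians and their age correlations) are computed over the 29 patients with
more than 3 HFOs: with all 30 patients the age–frequency correlation of
the rounded table is −0.46, clearly off the published −0.558, while the
morphology subset gives −0.576 and simultaneously matches the published
age–SNR and age–RBA coefficients. Second, the RBA–SNR correlation is
computed over all 30 patients, where it matches the published value to the
third decimal. Medians recomputed from the rounded table can differ
slightly from those printed from unrounded source data (overall rate 0.75
vs 0.77; older-group 0.65 vs 0.6); these are reported as computed.

## The synthetic EEG generator

The simulator works directly in bipolar derivation space — each channel is
an independent realization — which sidesteps any volume-conduction model.
Background = 1/f-weighted noise (exponent 1) scaled so that its
ripple-band RMS, measured with the package's own filter, hits the
configured target (default 1.5 µV, an N3-like scalp value), plus slow-wave
(0.5–2 Hz, 30 µV) and spindle (11–15 Hz, 8 µV, ~3/min) components that are
negligible in-band. Ripples are Tukey(0.5)-windowed sinusoids — the smooth
onset/offset mimics a physiological envelope while keeping duration
measurable — whose in-band peak-to-peak equals the configured amplitude.
Default ripple amplitude is 15 µV, chosen to straddle the SNR ≥ 4
detectability boundary on the default background rather than to match any
published amplitude distribution. Decoys comprise high-amplitude events
(55 µV ≥ the 40 µV ceiling) and mirrored homologous-pair events (30 µV:
below the ceiling so only the co-occurrence rule can reject them, and
strong enough to be detected on both hemispheres). A single integer seed
determines every draw.

Synthetic cohorts sample ages uniformly over 0.7–17.4 years; the injected
per-patient rate follows `5 · exp(−age/5)` HFO/min with log-normal noise
(sd 0.5), and the background RMS follows `1.9 − 0.05 · age` µV with
Gaussian noise, emulating the published negative rate–age and RBA–age
trends with realistic scatter. Recordings are materialized one patient at
a time to bound memory.

What the simulator does **not** emulate: volume conduction and electrode
cross-talk, real artifact morphology (muscle, electrode pops), hypnogram
structure beyond a single N3 block, spikes, and fast ripples. Passing
synthetic tests therefore demonstrates the internal correctness of the
pipeline under controlled conditions, not clinical-grade performance on
recorded EEG.

## Numerical choices and degenerate inputs

* S-transform via the FFT shifting identity; entropy scan samples the band
  every 5 Hz, Stage II profiles every 4 Hz — fine enough to resolve peak
  isolation at a fraction of the full-resolution cost.
* Time is 0-based in samples with half-open event spans `[onset, offset)`;
  touching spans do not overlap.
* Silent windows (zero power) take the maximum-entropy value by
  convention, so silent records produce a zero threshold and no events.
* All-zero signals, empty event lists, empty blocks, constant vectors and
  rank-deficient designs raise typed errors or documented sentinels rather
  than propagating NaN.
* EDF I/O uses 16-bit samples, 1-s records, a per-channel symmetric
  physical range, and a sidecar events table (BIDS style) for annotations.

## Problem sizes in the test suite

The suite exercises detection on 2–8 channel recordings of 1–5 min
(hundreds of thousands of samples per channel), cohorts of 30 patients at
the metadata level with end-to-end detection on a 6-patient subset, and
Monte-Carlo loops of 100–1000 replicates for the statistical oracles —
sizes chosen so the full suite runs in about a minute while every claim is
still backed by an independent oracle (brute-force enumeration, analytic
expectation, or ground-truth comparison).

## Known limitations

* The detector's Stage I/II constants are this implementation's defaults,
  not published values; clinical deployment would require recalibration
  against expert-marked events.
* Reliability is defined on the single top channel; focal-set definitions
  of the HFO area would need the pluggable alternative hook.
* The EDF reader supports the common single-rate 16-bit layout only.
* Statistics from the rounded per-patient table inherit its rounding; the
  package reports what it computes and treats published p-values as
  bounds.
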
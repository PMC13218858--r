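---
title: "Methods: multimodal physiology of interactive versus passive gameplay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal physiology of interactive versus passive gameplay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physioplay)
```

## The analysis problem

Active play of an emotionally challenging game scenario and passive
viewing of the same scenario plausibly produce different peripheral
physiological states: stronger cardiac activation with reduced
beat-to-beat variability, more frequent phasic electrodermal responses,
shallower and less regular breathing, a shifted skin-temperature
trajectory, and a different distribution of muscle activity across the
EMG spectrum. `physioplay` implements the full chain needed to test
this: event-based segmentation of five-channel 1000 Hz recordings (ECG,
EDA, RSP, EMG, TEMP), per-modality conditioning, an 80-feature windowed
extractor, FDR-controlled group comparison at participant level, and
window-level ridge-logistic discrimination between the two conditions
under participant-wise 10-fold cross-validation.

Because raw participant recordings from such experiments are typically
not shareable, the package ships a first-class synthetic-cohort
generator with complete ground truth. All calibration, recovery and
regression tests run against that generator; what they establish is
discussed at the end.

## Signal conditioning

Each channel is first z-scored per participant over the full recording
(population SD; a constant channel maps to zeros rather than failing).
Z-scoring before any filtering keeps the later absolute thresholds —
e.g. the electrodermal peak-prominence threshold — comparable across
participants.

All filters are zero-phase (forward–backward) 2nd-order Butterworth.
The family and order are a design choice: zero-phase filtering preserves
fiducial timing, which matters for R-peak and breath-onset placement.
Signals are de-meaned before filtering because the forward–backward pass
starts from zero state; without this a DC offset leaves long edge
transients at the very low cut-offs used here (low-pass filters get the
mean restored).

* **ECG** — baseline drift is removed by subtracting a two-stage running
  median (200 ms then 600 ms): the narrow QRS complex passes through the
  median cascade untouched while respiration- and movement-scale drift
  is captured and subtracted. R-peaks come from a Pan–Tompkins chain
  (5–15 Hz band-pass, five-point derivative, squaring, 150 ms
  moving-window integration, adaptive dual thresholds with 200 ms
  refractory and half-threshold search-back), with each detection
  refined to the local ECG maximum within ±50 ms. The integrator window
  is centred, so detections land near the R-wave before refinement.
* **EDA** — 0.02 Hz high-pass isolates phasic from tonic activity.
* **RSP** — 0.1–5 Hz band-pass; breath cycles are delimited at
  inspiration onsets (upward zero crossings of a 300 ms-smoothed copy,
  refined back to the raw crossing). A candidate cycle is accepted only
  if its exhaled excursion (peak minus following trough) reaches 65 % of
  the running median excursion over the preceding ten candidates. This
  acceptance rule is a documented surrogate for proprietary
  enhanced-pause (Penh) cycle screening: the exact semantics of that
  analysis are not public, so the 65 %-of-exhaled-volume threshold is
  operationalised as a relative excursion test. The first candidate has
  no history and is always accepted.
* **EMG** — anti-alias low-passed at 16 Hz and resampled on the exact
  32 Hz grid; 10 s of EMG then give the 320 samples that a 6-level
  wavelet decomposition divides cleanly.
* **TEMP** — z-scored only.

## Windowing and the 80-feature inventory

Features are computed in consecutive non-overlapping 10 s windows inside
annotated emotional-challenge events (incomplete tails are dropped;
half-open sample intervals make adjacent events partition cleanly). The
canonical inventory has 80 names — ECG 31, RSP 12, TEMP 8, EDA 12,
EMG 17 — so that dropping EMG leaves 63 features and dropping EMG and
EDA leaves 51. The inventory is reconstructed from those count
constraints plus the feature names that appear in the reported group
and screening tables; the remaining slots are standard HRV, respiratory
and temperature descriptors. `feature_names()` is the single canonical,
versioned list.

Notable definitions:

* `bpm` is the mean over beats of 60/RR, which by Jensen's inequality
  is at least 60 / (mean RR) with equality only for a metronomic heart.
* R-prefixed features (`R mean`, `R std`, `R mad`) describe R-peak
  *amplitudes* on the conditioned ECG, not RR dispersion — the
  RR-prefixed features carry that.
* HRV spectra use the RR tachogram (each interval at the time of its
  closing beat) resampled to 8 Hz by natural cubic spline inside a 32 s
  frame centred on the 10 s window and clipped to the event, mean-removed
  and zero-padded to 256 samples, giving 1/32 Hz bins. Bands are VLF
  0–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz; band power is the one-sided sum
  of squared magnitudes, PSD is power per Hz of bandwidth, and total
  power is VLF+LF+HF by construction. A window is skipped (features
  missing) when the clipped frame holds under 16 s of RR coverage. The
  32 s frame against a 10 s window trades frequency resolution for one
  spectral estimate per window; centring keeps the estimate aligned with
  the window it labels.
* EDA windows are decimated to a 20 Hz working rate (phasic activity
  lives far below that) and analysed in LF 0.02–0.5, HF 0.5–1 and VHF
  >1 Hz bands. Inside a 10 s window the LF edge is below the achievable
  resolution, so band-limiting uses exact FFT masks rather than very
  low-cut-off IIR filters, which are numerically fragile at 0.001 of
  Nyquist. "time sam" counts band-limited local maxima with topographic
  prominence ≥ 0.05 z-units; "frq sam" counts FFT bins above 10 % of the
  band's maximum bin power; both thresholds are exposed in
  `feature_config()`.
* EMG windows (320 samples at 32 Hz) are decomposed with a 6-level
  Daubechies-5 DWT using **periodization** boundary handling. With an
  orthonormal filter pair and a length divisible by 2^6 the transform is
  exactly orthogonal, so sub-band energies sum to the window energy to
  machine precision — the property the energy-proportion features rely
  on. Symmetric padding was considered and rejected: it inflates the
  coefficient count and breaks exact energy conservation. Level d1
  covers 8–16 Hz down to a6 below 0.25 Hz; the grouped slow-band share
  (`5–6 level (7) Eng%` = d5+d6+a6, everything below 1 Hz) is the
  fine-motor engagement marker, and `1–2 level Eng%` the fast-band
  complement. A tone on a dyadic band edge (e.g. 8 Hz) splits between
  adjacent levels; this is inherent to finite wavelet filters, not an
  implementation artefact.
* Missing features (too few beats or breath cycles in a window,
  zero-energy EMG) are propagated as `NA`, never silently imputed.

## Group statistics

Window values are averaged within each event and event means are
averaged per participant, so each event contributes equally regardless
of length ("one event-level estimate per participant"; with several
events per recording the second averaging stage is the natural reading).
Group comparisons use Student's pooled-variance t-test — group sizes are
equal by design and reported degrees of freedom in this literature
follow the pooled convention — with Cohen's d from the pooled SD and a
95 % confidence interval of the mean difference. P-values are adjusted
with Benjamini–Hochberg within declared families (by default all
physiological features form one family). Features constant in both
groups are flagged degenerate and excluded from testing. Supporting
questionnaire-style statistics (Mann–Whitney U with tie-corrected normal
approximation, Cronbach's α) are included as generic utilities.

## Classification

Discrimination is evaluated at window level with ridge-penalised
logistic regression under participant-wise 10-fold cross-validation:
participants are shuffled within condition under the seed, interleaved
across conditions and dealt to folds in contiguous blocks, so all
windows of a participant share a fold, fold sizes differ by at most one
(28 participants give eight folds of three and two of two), folds mix
conditions wherever their size allows, and both conditions appear in
every training set. Inside each fold, missing
values are mean-imputed and features standardised using training-fold
statistics only. The ridge penalty is fixed at unit L2 strength against
the summed log-likelihood (glmnet `lambda = 1/n` on standardised
features) — the regularisation strength is a documented default, not
tuned, chosen to stabilise 80 coefficients on a few hundred windows.
Accuracy is pooled over windows (correct windows / total windows), the
window being the classified unit. Ablations refit the identical folds
without EMG (63 features) and without EMG+EDA (51).

The single-feature screen fits each standardised feature alone on the
full data for its coefficient and a likelihood-ratio p-value
(BH-adjusted within the screen family), and reports cross-validated
accuracy on the shared folds. The likelihood ratio replaces the Wald
statistic because a feature that separates the classes (nearly)
perfectly drives the Wald standard error to infinity and its p-value
uselessly towards 1, while the LRT stays sharp; for well-behaved
features the two agree closely. Single-feature CV models are fitted
unpenalised.

## The synthetic cohort generator

`generate_recording()` draws one participant from a
`condition_profile()`: ECG places a fixed P–QRS–T Gaussian template
(amplitude 1 at R) at integrate-and-fire beat times; EDA adds
bi-exponential SCRs (0.75 s rise, 2 s decay — the canonical SCR shape)
at Poisson times over a sub-0.02 Hz tonic drift; respiration is a
quasi-sinusoid with breath-wise period and depth jitter plus wide-band
sensor noise; EMG is shaped noise whose spectral mass splits at 1 Hz
and whose in-event variance is scaled relative to the rest of the
recording; temperature is a bounded session ramp plus a slow random
walk. All randomness flows through one integer seed split into fixed
per-channel substreams: identical seeds give bit-identical recordings,
and the written CSV files round-trip losslessly because signals are
quantised to 1e-6 units at generation, far below every noise floor.
Each recording carries its ground truth (true beat times, SCR times,
breath onsets) and a four-event annotation table covering at least 60 %
of the session, placed in the later part of the recording where the
emotionally challenging quest unfolds. Event durations are a free
design choice — the source experiment does not report per-event lengths.
The default recording length is 300 s per participant (desk scale, not
the ~50 min of a full session), and the default cohort is 14
participants per condition with the narrative endings split 12:2.

The two shipped condition profiles encode the directions the study
design predicts, with active play showing: higher heart rate
(78.09 vs 74.16 bpm) and hence shorter RR; smaller beat-to-beat and
R-amplitude variability; shallower (1.05 vs 1.30 depth units) but less
regular (period jitter 0.55 vs 0.35 s) breathing; more frequent
(20 vs 12.5 /min) and larger SCRs; lower in-event gross EMG energy
(in/out variance contrast 0.75 vs 1.15) with a larger sub-1 Hz energy
share; and a stronger session temperature rise. Where a published group
mean maps directly onto a profile field (heart rate, its direction
partners) the printed value is used. Between-participant spreads are
deliberately moderate (e.g. 5 bpm between-participant heart-rate SD),
which makes per-feature standardised effect sizes of roughly 0.8–2 at
the participant level. This is a generator design decision: with the
spreads reported for real participants, several effects (notably
temperature, d ≈ 0.3) would flip sign in a third of 14-versus-14
cohorts, and a validation suite built on coin-flip directions tests
nothing. The generator therefore emphasises reliable direction recovery
at desk scale; real-data effect sizes are smaller and noisier than the
synthetic ones.

Two generator honesty notes. First, per-participant z-scoring erases
any between-condition difference that is constant within a recording,
so condition contrasts must be *structural*: the EMG energy difference
is carried by the in-event/out-of-event contrast, the temperature
difference by the ramp-versus-event-placement geometry, and the
respiratory depth difference survives only because sensor noise gives
the z-score denominator a depth-independent component. Second, the
relative-threshold "frq sam" counts are insensitive to the SCR rate by
construction (a stronger spectrum raises its own threshold), so the
generator makes no claim about their direction; the direction suite
covers the six benchmark features (bpm, RR mean, R std, HF time sam,
val mean, temp mean).

## What the tests establish — and what they do not

The validation suite checks, under fixed seeds: structural conformance
of the inventory (80/63/51); Pan–Tompkins sensitivity and positive
predictive value ≥ 0.99 against ground truth at ±50 ms on 300 s
cohorts; spectral correctness (a 0.1 Hz RR modulation concentrates
≥ 90 % of tachogram power in LF; total power equals the band sum
exactly; wavelet energies conserve window energy within 1e-6);
statistical calibration on null cohorts (per-feature t-test type-I
error within 0.05 ± 0.02 across 20 cohorts of 6 + 6 participants at
150 s; window-shuffled cross-validation within 0.50 ± 0.05 over 20
shuffles); direction recovery of the six benchmark features in ≥ 90 %
of ten 14 + 14 cohorts at 300 s, with the full multimodal model beating
the best single feature pairwise; and the leakage guard (no participant
ever splits across folds, and held-out windows never shape their own
fold's preprocessing). The reduced study sizes are stated here because
the properties involved — test calibration, detector operating point,
energy conservation — do not depend on cohort scale.

What passing does **not** show: that real gameplay physiology is as
cleanly separable as the synthetic cohorts (synthetic accuracies run in
the 90s; reported real-data accuracy is in the low 80s), that the
reconstructed feature inventory matches the unpublished original
item-for-item beyond the printed names and counts, or that the
generator's simplifications (no cardiorespiratory coupling, no motion
artifacts, no ectopic beats, identical physiology for both narrative
endings) are innocuous for any particular real dataset. The pipeline's
claims are about the *method*: its detectors recover known ground
truth, its statistics are calibrated, and its cross-validation cannot
leak participant information.

## Reproducing a run

```r
library(physioplay)
res <- run_pipeline("demo_run", default_config(seed = 17))
readLines("demo_run/report.txt")
```

`run_pipeline()` writes the cohort, feature matrix, group-comparison
table, cross-validation report and a run log; every derived output
embeds the configuration fingerprint and seed. `scripts/acceptance.R`
recomputes the headline numbers from scratch.
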
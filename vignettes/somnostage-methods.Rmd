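---
title: "Methods: epoch-based sleep staging and agreement estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epoch-based sleep staging and agreement estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnostage)
```

## The problem

Clinical sleep studies are scored by technologists who assign one of
five stages — wake (W), three non-REM depths (N1, N2, N3), and REM (R)
— to every 30-second epoch of a night's EEG/EOG/EMG recording, following
the AASM manual. Manual scoring is slow and scorers disagree with each
other appreciably, so automated scoring systems are validated by
quantifying their *agreement* with human experts, not their "accuracy"
against an absolute truth. This package implements that whole loop:
signal input, feature extraction, a trainable stage classifier, and the
agreement statistics used to judge it — plus a synthetic
polysomnography generator so that every component can be exercised and
tested without access to clinical recordings, which are rarely
shareable.

## Signals and the epoch grid

Recordings use the standard montage of six EEG derivations (F3-M2,
F4-M1, C3-M2, C4-M1, O1-M2, O2-M1), two EOG channels and one chin EMG,
stored in European Data Format (EDF). The EDF layer here writes 16-bit
samples against a fixed ±500 µV physical range in one-second data
records, and reading inverts that mapping, so round-trips are exact to
the ~0.015 µV quantization step. The epoch grid starts at the recording
start with half-open 30-s intervals; trailing partial epochs are
discarded rather than padded, and a recording shorter than one epoch
simply has zero epochs (this keeps the generator and the feature
extractor composable). When a file carries raw electrodes instead of
derivations, `compute_derivations()` forms them by sample subtraction;
pre-derived channels are always preferred.

## Feature extraction

Each 30-s epoch is sliced into 2-s sub-epochs with 1-s overlap — 29 per
epoch — sized so that transient N2 events (sleep spindles, ~13 Hz bursts
of 0.5–1.5 s; K-complexes, biphasic slow waves) dominate at least one
window. Per sub-epoch the power spectral density is estimated by the
multitaper method with time–bandwidth product `nw = 2` and `k = 3`
Slepian tapers: at 2-s windows this gives a ±1 Hz resolution bandwidth
with substantially lower variance than a raw periodogram, which matters
when 29 noisy estimates per epoch are summarised. The Slepian tapers are
computed from the standard symmetric-tridiagonal eigenproblem and cached.

Band powers (delta 0.5–4, theta 4–7, alpha 8–13, beta 13–30 Hz;
half-open intervals, the conventional 7–8 Hz gap left unassigned) are
integrated from the PSD and divided by the *epoch's* total 0.5–30 Hz
power (the mean over its 29 sub-epochs), so fractions are comparable
across sub-epochs, bounded, and invariant to overall amplitude scaling
— absolute EEG amplitude varies hugely across subjects and equipment.
PSDs of contralateral channel pairs are averaged before band
integration to reduce sensor noise; since the average is symmetric,
swapping left and right channels cannot change a feature. Delta/theta,
theta/alpha and delta/alpha ratios are formed per sub-epoch with an
additive `1e-12` denominator guard. Line length (sum of absolute
successive differences) and Pearson kurtosis (`m4/m2²`, which errors on
zero-variance windows) are computed per sub-epoch on each channel and
contralaterally averaged; computing them per sub-epoch rather than once
per epoch keeps every feature on the same 29-point track and lets the
summaries capture within-epoch transients. Every track is summarised by
its 95th percentile (linear interpolation between order statistics, the
default quantile definition in R), minimum, mean and sample (n−1)
standard deviation — these four summaries, not the tracks, form the
feature vector.

EOG channels contribute the integrated 0.3–5 Hz PSD per sub-epoch,
averaged over the available EOG channels: that band spans slow rolling
eye movements (drowsiness) through rapid eye movements (REM), and its
width is configurable because "eye-movement energy" has no canonical
band. The chin EMG contributes its mean-squared amplitude after mean
removal. The resulting vector has 116 named entries — 3 sites × 9
features × 4 summaries + 4 EOG + 4 EMG — in the fixed order given by
`feature_layout()`, which doubles as the layout fingerprint that
trained models check at prediction time. Dead-channel epochs (total
power below the guard) are flagged and zero-filled rather than dropped,
so epoch indices stay aligned with the hypnogram.

## The classifiers

Three small variants share a weighted softmax cross-entropy head and
full-batch Adam training with analytic gradients:

* **conv** — a 1-D convolution (12 filters, kernel 5) over the ordered
  feature axis within each epoch, ReLU, then concatenated mean- and
  max-pooling over positions (the mean carries the broad profile, the
  max responds to isolated strong activations such as a single shifted
  summary block) and a dense softmax; each epoch is classified
  independently.
* **recurrent** — an Elman recurrence (hidden size 16) over the epoch
  sequence, softmax per epoch; this is what lets stage *context*
  (e.g. N2 continuity) influence a label.
* **conv_recurrent** — the conv encoder feeding the recurrence.

These are deliberately desk-scale (well under 10⁵ parameters,
CPU-minutes to train): the architecture is a contract for how temporal
context and within-epoch structure enter the model, not an attempt to
reproduce any particular production network. Class weights default to
inverse frequency because stage imbalance is severe in clinical cohorts
(N3 can be a few percent of epochs); features are standardised with
training-set statistics stored in the model. Everything is seeded and
full-batch, so a fixed seed and fixed data give bit-identical models
and predictions; argmax ties break by the fixed stage order W, N1, N2,
N3, R. Splitting is always by subject — epochs within a recording are
strongly dependent and splitting them across train/test would leak.
Model selection takes the candidate with the highest pooled validation
kappa (kappa, not accuracy, since kappa is the headline agreement
metric), breaking ties toward fewer parameters and then earlier
registration.

`apply_continuity_smoothing()` is an optional post-processor encoding
one AASM-motivated rule: a single N1 epoch flanked by the same stage S
∈ {N2, R} on both sides is relabelled S, reflecting how scorers carry
N2/R across low-amplitude mixed-frequency epochs. Longer N1 runs are
left alone, and the rule is idempotent. The full AASM transition
rulebook is out of scope.

## Agreement statistics

`confusion_matrix()` counts reference stage (rows) against candidate
stage (columns) in the fixed stage order. Cohen's kappa is
`(p_o − p_e)/(1 − p_e)`; when both scorers are constant on the same
category `p_e = 1` and kappa is reported as undefined rather than a
number. The interpretation scale defaults to the Landis–Koch
breakpoints (0, 0.20, 0.40, 0.60, 0.80 with right-closed intervals);
the breakpoints are user-replaceable because published variants of this
scale differ.

Per-stage agreement uses the 2×2 collapse (a = both scored the stage,
b = reference only, c = candidate only, d = neither): positive specific
agreement `PA = 2a/(2a+b+c)`, negative specific agreement
`NA = 2d/(2d+b+c)` (the Cicchetti–Feinstein definitions), and binary
overall agreement `OA = (a+d)/n`. Pooled ("Total") PA and NA aggregate
the collapses' numerators and denominators across the five stages —
which makes total PA algebraically equal to the plain observed
agreement `p_o` — while total OA is the five-stage mean of the binary
overall agreements. Undefined denominators yield undefined markers, not
NaNs.

Confidence intervals come from a subject-level bootstrap: subjects (not
epochs) are resampled with replacement R = 1000 times, each resample's
confusion matrices are pooled, and every metric's point estimate and
95% CI are the median and 2.5/97.5 percentiles of its resample
distribution. Epochs within a subject are dependent, so resampling
subjects is the defensible unit; a metric undefined in more than half
the resamples is reported undefined with a diagnostic. The per-subject
kappa distribution (median/mean/SD/min/max) is also reported, since a
pooled kappa can mask heterogeneity. Reports carry full precision;
printing rounds half away from zero to integer percents, matching how
such tables are conventionally published.

The package ships the row-percentage confusion table and per-stage
epoch counts from a published clinical validation of automated scoring
(`clinical_reference_tables()`). Multiplying the rows by the counts
reconstructs the pooled count matrix those tables imply; the
reconstruction reproduces the published total PA (90%), W-stage PA
(95%) and mean overall agreement (96%), and it doubles as a realistic
scorer-noise model for simulations. The cross-table reconstruction is
only internally consistent for the W and total rows — the published
per-stage OA entries for N1, N3 and R cannot all be recovered from the
row percentages — so only those reconstructable quantities are treated
as checks.

## The synthetic generator

`generate_hypnogram()` draws stages from a first-order Markov chain
with transition matrix `P = s·I + (1−s)·1πᵀ`: with probability `s` the
stage repeats, otherwise the next stage is drawn from the target law π
itself, so π is *exactly* stationary for every stickiness `s` (verified
against an eigen-decomposition in the tests) and the mean run length of
stage i is `1/((1−s)(1−π_i))`. The default `s = 0.9` gives bouts of
roughly 3–20 epochs (1.5–10 min) depending on the stage's mass,
qualitatively like human sleep-bout structure. The default π is the
cohort mean reported for a large adult clinical population: W 16.5%,
N1 15.2%, N2 50.2%, N3 2.7%, R 15.4% of scored epochs. Chains start in
W (or the first stage with positive mass when W has none). Real
hypnograms are not first-order Markov — they have nightly architecture
(sleep cycles, REM periodicity) this model ignores; it reproduces
stage proportions and bout lengths, which is what the agreement and
training machinery is sensitive to.

`synthesize_record()` renders a hypnogram into the nine-channel
montage. Each stage has a spectral recipe: W is alpha-dominant with an
occipital gradient, high chin tone and occasional blinks; N1 is
low-amplitude mixed-frequency theta with slow rolling eye movements;
N2 adds sleep spindles (13 Hz Gaussian-enveloped bursts, 2 per epoch,
central-dominant) and K-complexes (biphasic slow waves, 1 per epoch,
frontal-dominant) on the theta background; N3 is high-amplitude delta
with a frontal gradient; R is LAMF with conjugate (mirrored) rapid eye
deflections and minimal chin tone. Contralateral channels share the
site waveform and differ by independent sensor noise, so contralateral
averaging genuinely reduces noise in the synthetic data exactly as
intended on real data. About 20% of subjects (configurable) use an
alpha-suppressed W recipe, mimicking the sizeable minority of people
with little or no waking alpha rhythm — the known hard case for W/N1
discrimination. Per-subject stage proportions are jittered by a
Dirichlet with concentration 10 around the cohort means; that value is
a design choice giving between-subject spreads of the same order as
clinical cohort SDs (a single concentration cannot match all five
published SDs at once). All randomness derives from a master seed with
fixed per-subject, per-purpose sub-seeds, so adding a draw in one
component cannot perturb another and cohorts are byte-identical across
runs.

What passing tests on this generator do **not** show: performance on
real EEG, with its artifacts, inter-subject spectral variability,
arousals, and scorer idiosyncrasies. The synthetic end-to-end result
(held-out kappa ≥ 0.7 on a 30-subject cohort) demonstrates that the
pipeline is correctly wired and that the features carry the constructed
stage information — it is a synthetic analogue, not a claim about
clinical agreement levels.

## Numerical choices and problem sizes

Degenerate inputs are guarded, not silently propagated: zero total
power errors (or flags the epoch inside `extract_features()`),
zero-variance kurtosis errors, empty confusion rows give undefined
markers, and `p_e = 1` kappa is undefined. The percentile definition
(R type 7), sample SD, half-away-from-zero printing, eps = 1e-12
guards, and the fixed stage order are all pinned so that results are
reproducible to the bit. The test suite runs its end-to-end check on a
30-subject cohort of 120-epoch (1-hour) recordings and its bootstrap
coverage check on 200 trials of 15 subjects × 200 epochs with R = 200
resamples — sizes chosen so the whole suite completes in CPU-minutes
while keeping every statistical check comfortably powered; the
acceptance script's synthetic calibration uses 200 subjects × 960
epochs (full nights).

## Known limitations

* The EDF writer targets the package's own fixture needs: integer
  sampling rates, one-second records, a fixed physical range; EDF+
  annotations are not parsed.
* The classifiers are desk-scale and feature-based; raw-signal
  end-to-end models and GPU training are out of scope.
* Agreement statistics cover exactly two scorers; multi-rater kappa
  variants and event-level agreement are not implemented.
* The synthetic generator models spectral signatures and stage bouts,
  not full sleep architecture or respiratory events.
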
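---
title: "Methods: knowledge-based staging of forehead sleep EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-based staging of forehead sleep EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepstager)
```

## The problem and the model

Sleep is staged visually: an expert reads each 30-s epoch of EEG and
assigns one of W, N1, N2, N3 or REM following the AASM rules, which are
phrased in terms of rhythms and transients — "more than 50% of the epoch
has alpha rhythm" (W), theta replacing alpha (N1), sleep spindles
(12–14 Hz bursts of 0.5–1.5 s) or K-complexes (biphasic transients of at
least 0.5 s) on a theta background (N2), and high-amplitude slow-wave
activity over more than 20% of the epoch (N3). The package automates this
on the two frontopolar channels FP1/FP2 — the sites a self-applied
headband can record — with a pipeline of band-pass filtering, short-time
spectral feature extraction, per-feature standardization, and a sparse
Bayesian kernel classifier, evaluated leave-one-subject-out.

The central design idea is that a whole-epoch Fourier transform averages
away exactly the evidence the rules use: a single 1-s spindle contributes
1/30 of a 30-s spectrum and disappears into the background. The extractor
therefore computes a spectrogram of 59 half-overlapping 1-s segments and
summarizes the *distribution over segments* of each band's relative
power, instead of its epoch mean.

## Feature extraction

Each channel of a filtered epoch is windowed (1-s Hamming, 0.5-s step,
giving `floor((3840-128)/64)+1 = 59` segments at 128 Hz) and turned into
one-sided periodograms with 1-Hz bin spacing. Every segment is divided by
its own total power. This makes all downstream features dimensionless
proportions in [0, 1] and — because an amplitude gain multiplies every
bin equally — exactly invariant to the inter-individual scalp-gain
differences that otherwise dominate between-subject variance. The
amplitude criterion of the slow-wave rule (> 75 µV) is therefore not
representable after normalization; slow-wave activity is carried entirely
by the *relative* lower-delta power, which is what the normalization
trades for subject invariance.

From each band's 59-point series the extractor computes statistics
matched to the rules' temporal character, 13 per channel (26 total):

| band (Hz) | statistic | rule it encodes |
|---|---|---|
| lower delta 1–2 | mean of upper / lower 80% of segments | slow-wave occupancy (N3) |
| delta 1–4 | max + mean of remaining 58 | K-complex (N2) |
| theta 5–7 | mean of upper / lower 50% | light sleep (N1/N2/REM) |
| alpha 8–12 | mean of upper / lower 50% | relaxed wake |
| sigma 12–14 | max + mean of remaining 58 | sleep spindle (N2) |
| beta 15–30 | mean of upper / lower 50% | alert wake |
| gamma 30–50 | mean of all 59 | movement/muscle artifact |

Sorted-fraction means use `k = max(1, floor(fraction * 59))` values (47
at 80%, 29 at 50%); the max/rest statistics remove one occurrence of the
maximum. Band edges are inclusive at the 1-Hz bin resolution. The lower
delta band is 1–2 Hz: the analysis window makes 1 Hz the finest bin, so a
0.5-Hz edge would not change the selected bins; the edge is configurable.
The conventional baseline extractor computes one periodogram of the whole
epoch, aggregates it into 50 one-Hz bands centered at 1..50 Hz per
channel, and by default normalizes by total 1–50 Hz power so it shares
the scale invariance (a switch returns the raw PSD).

Counting the enumerated statistics gives 13 per channel; the schema is
exposed by name so alternative sets can be added. Before any classifier,
features are z-scored with means and SDs estimated on training data only
— kernel and distance methods need commensurate scales, and estimating
the standardizer on the training fold keeps test subjects untouched.

## The classifier

The relevance vector machine is a kernel classifier with an independent
Gaussian prior N(0, 1/α_i) on every kernel weight (and the bias). For
fixed α the posterior mode of the weights under the logistic likelihood
is found by Newton/IRLS with step halving; the Laplace approximation
around the mode gives the posterior covariance Σ, and the evidence update
α_i ← γ_i/µ_i² with γ_i = 1 − α_iΣ_ii re-estimates each hyperparameter.
Weights whose α exceeds 10⁹ are pruned; the surviving training points are
the relevance vectors. Regularization is thus estimated automatically —
unlike a margin classifier there is no penalty constant to cross-validate,
and the retained model is typically far smaller than the training set.
Numerical choices (the defaults; all exposed as arguments): α initialized
to 10⁻², convergence when max |Δ log α| < 10⁻³, at most 500 update
cycles, IRLS capped at 25 steps per cycle, Cholesky solves with a
diagonal jitter fallback. Non-convergence at the cycle cap is recorded in
the model metadata rather than raised: the pruned model is still usable,
and on noisy folds the α of borderline basis functions can drift
indefinitely without changing predictions materially.

Multiclass wrapping is one-against-all in the fixed order W, N1, N2, N3,
REM: five binary models, prediction by the largest posterior probability,
exact ties to the earliest stage. The RBF kernel uses
exp(−γ‖·‖²) with γ = 0.5 (the σ parameterization is γ = 1/(2σ²)).
Baselines behind the same interface: LDA (pooled-covariance Gaussian
discriminant, ridge 10⁻⁶·tr(S)/d added only when the covariance is
near-singular), k-NN with k = 13 (vote ties to the class of the nearest
tied neighbor), and an SVM from the e1071 package with cost 50 — an
established implementation is used there deliberately, since the margin
classifier serves only as a comparison point.

## Evaluation protocol

Evaluation is leave-one-subject-out: the standardizer and classifier are
fitted on n−1 subjects and applied to the held-out subject, so test
subjects are never seen during training — the appropriate protocol when
the goal is a subject-independent model, where within-subject k-fold
splits would leak subject identity. Reports carry per-subject accuracy
and unweighted Cohen's kappa κ = (p_o − p_e)/(1 − p_e), their
across-subject mean ± SD, and the pooled confusion matrix with pooled
metrics (both conventions are useful; they differ when subjects have
unequal nights). Sensitivity of a stage absent from a subject's night is
reported missing and excluded from averages. Separability of a feature
set is measured by the scatter-matrix ratios J1 = tr(S_b)/tr(S_w) and
J2 = tr(S_w⁻¹S_b); J2 is invariant to any invertible linear map of
feature space, J1 to orthogonal maps and global rescaling. Because J1 is
not invariant to per-feature rescaling, it is only meaningful under a
scale convention; `feature_separability()` therefore evaluates both
criteria on the z-scored feature table — the representation every
classifier in the package consumes — which leaves J2 unchanged (the
transform is diagonal and invertible) and makes J1 comparable across
feature sets of different dimension and unit.

## The synthetic cohort

No public recordings accompany the package, so a seeded simulator
provides stage-labeled data. Each stage has a recipe: a dominant
band-limited Gaussian carrier windowed to a random contiguous stretch of
the epoch, always-on background carriers, transient events with Poisson
counts and raised-cosine envelopes, and a 1/f-plus-white noise floor
(18 and 6 µV RMS). Everything except the white sensor noise is shared
between the two channels; eye movements enter them with opposite sign,
as the frontopolar derivations see them. Occupancies are drawn per epoch
from a range whose lower end is the rule's threshold (W/N1/N2 rhythms
50–95%, N3 slow waves 20–50%), every component amplitude gets
independent per-epoch log-normal jitter (SD 0.3), and each subject
applies a global log-normal gain (SD 0.2) to all amplitudes — the
nuisance the per-segment normalization exists to remove. Event rates:
0.5 spindles and 0.5 K-complexes per N2 epoch (about one event every two
epochs), 3 eye movements per REM epoch (a free parameter: the rules give
no quantitative REM criterion for these channels). Stage labels are
drawn i.i.d. from the prevalence prior W 18.4%, N1 13.1%, N2 37.8%,
N3 15.6%, REM 15.1% — the pooled distribution of a healthy-adult
overnight cohort. Per-subject RNG substreams are derived from the master
seed by a fixed integer recurrence, so cohorts regenerate identically
and adding a subject never perturbs earlier ones.

What the simulator does *not* emulate: artifacts (the pipeline applies no
artifact rejection), stage-transition dynamics (labels are i.i.d., not a
Markov chain — sufficient for classification tests, wrong for
hypnogram-morphology studies), arousals, and any waveform realism beyond
band content and event envelopes. Passing tests on this cohort therefore
demonstrate that the pipeline recovers stages whose spectral structure
follows the scoring rules — not clinical-grade performance on real
patients, which only real recordings can establish.

## Problem sizes and numerical notes

The packaged evaluation runs use a 10-subject cohort of 50 epochs per
night for the LOSO comparison and 20 subjects × 100 epochs for the
prevalence check; these sizes keep a full run to a few minutes while
leaving every training fold with all five stages present. On this cohort
the knowledge-based features yield higher J1 and J2 and clearly higher
LOSO accuracy than the conventional whole-epoch baseline, with the
advantage concentrated where the design predicts it: stages
distinguished by transients (N2) and occupancy (N3) rather than by mean
spectra. Degenerate inputs are explicit errors rather than silent
results: all-zero segments cannot be normalized, bands outside the
available bins are rejected, single-class training sets and folds
missing a stage name the offender. EDF encoding uses a symmetric 16-bit
digital range so a zero signal round-trips exactly and the round-trip
error is bounded by one quantization step. Trailing partial epochs are
dropped with a message; epoch i is paired with hypnogram label i
(0-based) from the recording start, and label/epoch count mismatches are
tolerated up to a configurable slack (default 5 epochs) before becoming
errors.
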
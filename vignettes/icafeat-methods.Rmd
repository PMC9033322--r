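---
title: "Methods: fixed-point ICA and entropy features for two-class EEG"
author: "icafeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-point ICA and entropy features for two-class EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icafeat)
```

## The problem

Multichannel EEG is a linear, instantaneous mixture of underlying cortical
and non-cortical sources: what an electrode records is a weighted sum of
whatever is active under and around it, plus broadband noise. Features
computed directly on channels therefore mix the process of interest with
everything else. `icafeat` implements a feature-extraction pipeline for
two-class (calm vs. pressure) emotion recognition that (i) optionally
unmixes the channels with fixed-point independent component analysis (ICA),
(ii) computes rhythm-band energies and an entropy family per unit (channel
or component), and (iii) evaluates the features with a cross-validated
linear support-vector machine, overall and per unit.

Everything is validated on synthetic data generated by the package itself,
with full ground truth; no external recordings are required.

## The mixing model and whitening

The observation model is $x(t) = A\,s(t)$ with $x \in \mathbb{R}^m$ the
channels, $s \in \mathbb{R}^k$ statistically independent sources, and $A$
an unknown mixing matrix. Sources are identifiable only up to permutation
and scale, which is why recovery is scored with scale-free criteria
(absolute Pearson correlation, the Amari index).

`fit_whitening()` centres each channel (the covariance of uncentred data is
not meaningful, so centring is always applied) and eigendecomposes the
sample covariance $C = E D E^\top$. The whitening transform is the PCA form
$V = D^{-1/2} E^\top$, which makes truncation to the leading `n_keep`
components well defined; the symmetric whitener $E D^{-1/2} E^\top$ differs
from it only by a rotation that the subsequent ICA rotation absorbs.
Whitened data have identity covariance, verified to `1e-6` (max absolute
deviation) on every fitted model in the test suite.

## The fixed-point iteration

Non-Gaussianity of a projection $w^\top z$ (with $z$ whitened, $\|w\| = 1$)
is measured by the negentropy approximation
$J(w) = [\,\mathrm{E}\,G(w^\top z) - \mathrm{E}\,G(\nu)\,]^2$, $\nu \sim
N(0,1)$, with the logcosh contrast $G(u) = \log\cosh(a_1 u)/a_1$,
$g(u) = \tanh(a_1 u)$, $a_1 \in [1, 2]$ (default 1). Setting the gradient of
the Lagrangian to zero and applying one approximate Newton step — using
$\mathrm{E}[z z^\top g'(w^\top z)] \approx \mathrm{E}[g'(w^\top z)]\,I$,
valid for whitened data — gives the fixed-point update

$$w^{+} = \mathrm{E}[\,z\,g(w^\top z)\,] - \mathrm{E}[\,g'(w^\top z)\,]\,w,
\qquad w \leftarrow w^{+} / \|w^{+}\|,$$

in which the Lagrange multiplier has cancelled. Expectations are sample
means. Convergence is declared when $|\langle w_{\text{new}},
w_{\text{old}}\rangle| > 1 - \text{tol}$ (default `tol = 1e-6`, `max_iter =
200`); the absolute value absorbs the sign flips the update is allowed to
make. $\mathrm{E}\,G(\nu)$ is computed once per nonlinearity by 40-node
Gauss–Hermite quadrature; it only affects the diagnostic contrast value,
never the update.

Design choices that were genuinely open:

* **Orthogonalisation.** Components are extracted one at a time
  (deflation), Gram–Schmidt-orthogonalising the running direction against
  accepted rows after *every* update; symmetric (simultaneous)
  orthogonalisation is available via `ortho = "symmetric"`. Deflation was
  chosen as the default because the one-unit update is the primitive the
  derivation produces, and per-component iteration counts and convergence
  flags are then meaningful.
* **Initialisation and reproducibility.** Each direction starts from a
  seeded standard-normal draw; `seed` is a required argument everywhere
  randomness enters (`fit_ica()`, the generators, `evaluate()`), and no
  function touches the global RNG without setting it.
* **Sign convention.** Each row of $W$ is flipped so its component has
  positive skewness (falling back to the sign of the largest-magnitude
  sample), making output deterministic for testing.
* **Degeneracies.** A zero-norm update triggers reinitialisation from the
  seeded stream with a message; non-convergence after `max_iter` flags the
  component and warns but still returns — the caller decides.

Recovery is validated on a three-source benchmark (8 Hz sine, 13 Hz
sawtooth, uniform noise; 60 s at 128 Hz; seeded random $3 \times 3$ mixing,
no sensor noise): every recovered component matches its source with
$|r| \ge 0.95$ (observed: $> 0.999$) and the Amari index of
$(W V) A_{\text{true}}$ is $\le 0.05$ (observed: $\approx 0.01$–$0.02$).
The Amari index used here is normalised to $[0, 1]$ and is zero exactly on
scaled permutations.

## Epoching

Trials follow a fixed timing rule (`trial_spec()`): by default a 63-s epoch
of which the last 40 s — $[23, 63)$ — are analysed, divided into
non-overlapping 5-s windows, with any remainder shorter than one window
dropped. The early part of an epoch is discarded as unstable, a routine
practice; all three numbers are configuration. Sample indexing is 0-based
with half-open windows $[start, end)$ and fractional boundaries rounded to
the nearest sample; this removes boundary ambiguities that timing rules
stated in seconds otherwise leave open. No filtering, re-referencing,
resampling or artifact rejection is performed.

## Spectral features

Per window and channel, the mean is removed and the raw periodogram taken
(single taper, no zero padding, no within-window Welch averaging — the
averaging *across* a trial's windows already plays that role). Band energy
sums the periodogram over bins in $[f_{lo}, f_{hi})$; the total is the
power over all bins in $(0, f_s/2]$, and relative energy is band/total.
One convention needed inventing: intervals are half-open, *except* that a
band whose upper edge equals the Nyquist frequency also receives the
Nyquist bin — without this no band scheme could partition the spectrum
exactly, and the Parseval check (band energies summing to the total within
`1e-9` relative for a covering scheme) could never hold.

The default scheme is delta $[1,4)$, theta $[4,8)$, alpha $[8,13)$, beta1
$[13,16)$, beta2 $[16,20)$, beta3 $[20,30)$, gamma $[30,45)$ Hz. The beta
sub-band edges have no universal standard; these are configuration, logged
with every run. Note the default scheme deliberately does *not* cover
$(0, f_s/2]$ (it omits $<1$ Hz and $>45$ Hz), so its relative energies sum
to slightly less than one; the sum-to-one identity applies to covering
schemes only.

An all-constant window has zero total power; it is flagged degenerate, its
relative energies are undefined (`NA`), and `average_band_features()`
excludes it with a count rather than poisoning the trial mean.

## Entropy features

The entropy family uses the canonical published definitions, since the
application domain fixes only their names, with defaults $m = 2$,
$r = 0.2\,\mathrm{SD}$, scales $1\ldots10$:

* **Sample entropy**: $-\log(A/B)$ over the same $n - m$ template start
  points for both lengths, Chebyshev distance, self-matches excluded. When
  $A = 0$ or $B = 0$ the statistic is undefined and returned as a flagged
  `NA` — never a silent infinity; rows carrying undefined entropies are
  dropped (with a count) before classification.
* **Approximate entropy**: $\Phi_m(r) - \Phi_{m+1}(r)$ with self-matches
  included, hence always finite.
* **Composite multiscale entropy**: at scale $\tau$, the mean of sample
  entropy over all $\tau$ coarse-graining offsets, with $r$ fixed from the
  original series' SD. At $\tau = 1$ it reduces — bit-identically, by
  construction and by test — to sample entropy.

Entropies are computed on each channel's full analysis segment rather than
per 5-s window: with $m = 2$ and 640-sample windows the estimates are
unstable, and the per-window option adds variance without information. The
$O(n^2)$ template matching is implemented in C++; an independent brute-force
R implementation in the test suite must agree exactly on every fixture with
$n \le 200$.

## The synthetic data generator

`make_emotion_dataset()` generates what the validation needs and nothing
more: per trial, one *bursty* band-limited latent component per rhythm band
(a band-limited Gaussian carrier multiplied by a slow positive envelope),
mixed into channels through a spatial pattern drawn once per dataset, plus
per-channel pink ($1/f$) background noise. The two classes share the whole
recipe except stated multiplicative gains on named bands — the default
pressure class doubles the beta sub-band components, encoding the
phenomenon the classifier is supposed to detect: under pressure, beta-band
energy increases.

Three generator features deserve justification, because plain "band-limited
noise through a random matrix" would invalidate the validation itself:

* **Burstiness.** A band-limited Gaussian process is Gaussian, and ICA
  cannot separate Gaussian sources at all — the whole identifiability of
  the model rests on non-Gaussianity. Real EEG rhythms wax and wane in
  bursts and are leptokurtic; the amplitude modulation reproduces that and
  makes the benchmark solvable in principle.
* **Per-trial rhythm power jitter** (`rhythm_jitter_sd`, log-normal).
  Without it, any nonzero class gain is perfectly separable and every
  classification benchmark saturates at 1.0, which tests nothing. Real
  band power fluctuates substantially between trials.
* **A spatially low-rank artifact source** (`artifact_level`,
  `artifact_jitter_sd`, `artifact_band`): one bursty source — broadband
  pink or band-limited, e.g. muscle noise overlapping beta — projected onto
  *all* channels with random signs and magnitudes bounded away from zero
  (volume conduction spreads artifacts over every electrode), with large
  trial-to-trial power jitter. This is the interference ICA exists to
  remove.

Ratings are drawn from class-specific truncated normals on the 1–9
valence/arousal scale (calm centred at valence 5 / arousal 2.5, pressure at
2 / 7, SD 0.8), so the box-labelling rule recovers the true class for most
trials and its discard zone is genuinely exercised (roughly 10–20% of
trials fall outside both boxes at these settings).

What the generator does **not** emulate: realistic head geometry or
electrode montages, non-stationarity within a trial, line noise, ocular
waveforms with their characteristic shapes, inter-subject variability.
Passing tests therefore demonstrate the pipeline's correctness and its
behaviour under the stated generative assumptions — not performance on real
recordings.

## Labelling and classification

`label_rule()` maps ratings to classes by closed-interval box membership:
by default calm is valence $\in [4,6]$ and arousal $\in [1,4]$, pressure is
valence $\in [1,3]$ and arousal $\in [5,9]$, everything else is discarded.
Published studies rarely state their thresholds; this geometry (calm =
mid-valence/low-arousal, pressure = low-valence/high-arousal) is a
configuration default, not a claim of fidelity, and is logged with every
run.

`evaluate()` runs stratified k-fold cross-validation (default $k = 5$) of a
linear-kernel SVM with $C = 1$ and per-fold feature standardisation using
training-fold statistics only. No hyperparameter search is performed. Folds
are seeded; the whole report is deterministic given `(features, labels,
seed)`. `evaluate_per_channel()` repeats the evaluation with each unit's
feature block alone, and `compare_conditions()` pairs two seed-matched
reports fold by fold, reporting the mean difference and a sign summary —
deliberately no significance test, as five paired folds cannot support one.

## The ICA-vs-raw comparison

A finding worth stating plainly: when the class signal lives in band
*power* and full multichannel feature vectors are used, ICA-component
features and raw-channel features are close to linearly equivalent —
channel band energies are approximately linear images of source band
powers, so a linear SVM can compensate for spatial mixing on its own, and
replicated runs show no systematic difference between the conditions.

Where unmixing demonstrably pays off is the *channel-selection* setting the
pipeline targets: classify from one unit (one channel, or one component) at
a time. A single channel cannot cancel an artifact it shares with the
signal; a single separated component can be clean. The frozen
`selection_benchmark_spec()` — 8 channels, 30 trials/class, 15-s trials,
beta2 gain 2.0, rhythm jitter 0.3, a beta-overlapping (14–32 Hz) artifact
at level 8 with power jitter 1.0, pink background 0.3 — makes this
concrete: on replicated datasets the best single ICA component classifies
substantially better than the best single raw channel (the README's worked
example shows 0.917 vs. 0.646 at one seed). `run_selection_benchmark()`
reproduces this comparison end to end, and the acceptance script reports
the mean best-unit accuracies of both conditions over five replicate
datasets.

## Problem sizes

The test and acceptance workloads use deliberately small instances chosen
as the smallest that exercise each property with comfortable margins: the
three-source 60-s separation benchmark for recovery; 10–15-s trials with
2–8 channels and 10–30 trials per class for the classification properties
(the separable check uses beta gain 3, the null check 20 replicate datasets
of 20 trials each, pooled); 5 replicate datasets for the selection
comparison; entropy oracle fixtures up to $n = 200$ and production series
up to a few thousand samples. The full-size layout the generator defaults
emulate (32 channels, 40 trials, 63-s epochs) runs through the identical
code paths.

## Known limitations

* Deflation accumulates estimation error into later components; for large
  channel counts symmetric orthogonalisation is usually preferable and is
  provided, but the default stays faithful to the one-unit derivation.
* The negentropy contrast at a converged direction is a *local* maximum;
  later deflated components are constrained to an orthogonal complement and
  may sit below an unconstrained random direction's contrast. Tests assert
  dominance of the best component, not of every component.
* Sample entropy is undefined (flagged `NA`) on series with no template
  matches; strongly trending series with small $r$ are the typical cause.
* EDF support covers plain continuous EDF with a single sampling rate;
  EDF+ discontinuous records and annotations are out of scope.
* The SVM is intentionally minimal (linear, $C = 1$, no tuning); the
  evaluation harness measures feature quality, not attainable accuracy.
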
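---
title: "Band-power decoding of finger movements: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Band-power decoding of finger movements: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdecode)
```

## The decoding problem

Voluntary finger movements modulate the Mu (~8–13 Hz) and Beta (~13–30 Hz)
rhythms recorded over the sensorimotor cortex. Because thumb, index-finger
and fist movements originate in nearly the same cortical territory, their
scalp signatures differ only subtly — mostly in how strongly the 8–30 Hz
band power changes at the frontocentral channels F3 and FC5 of the
14-channel Emotiv montage. `eegdecode` implements the complete decision
chain of an embedded decoder built around exactly that contrast: replayed
250 ms chunks, an 8–30 Hz zero-phase Butterworth band-pass, Hamming-windowed
periodogram band power per channel, a two-stage binary logistic network, and
a mapping from the decoded class to two prosthesis motor states.

The package assumes: a fixed 14-channel montage in a canonical order (all
feature indices and classifier weights refer to it); 128 Hz sampling;
chunk-wise processing with no state carried between chunks; and band power
as a sufficient statistic for the class, i.e. phase information is
deliberately discarded.

## Signal chain and numerical choices

### Chunking

`stream_chunks()` cuts a trial into consecutive, non-overlapping 32-sample
(250 ms) chunks. A trailing remainder shorter than one chunk is discarded
rather than zero-padded: the embedded loop only ever processed complete
reads, and zero-padding would bias the band-power estimate of the final
chunk downward. A 10 s trial therefore yields exactly 40 chunks.

### Filtering

The band limiter is a cascade of two order-2 digital Butterworth sections —
high-pass at 8 Hz, low-pass at 30 Hz — run through the direct-form
difference equation with zero initial conditions. Two coefficient sources
exist on purpose:

* the **embedded profile** (default) uses the 4-decimal constants the
  original firmware shipped (`butter_table_coefficients()`), so the desktop
  output matches what the device computed;
* the **design profile** rederives full-precision coefficients from the
  analog Butterworth prototype by bilinear transform with frequency
  prewarping (`design_butterworth()`); at (2, 8 Hz, 128 Hz) and (2, 30 Hz,
  128 Hz) the rounded results reproduce the shipped constants.

Zero-phase response is obtained by filtering forward, reversing, filtering
again and reversing back. The source material for this pipeline says only
that the signal "was padded"; the padding scheme is therefore a design
choice here: odd (antisymmetric) reflection of 3·(order+1) = 9 samples at
each end, the de-facto standard for forward–backward IIR filtering, which
continues the signal without a jump in value or slope and absorbs the
filter's start-up transient. The pad length is configurable
(`zero_phase_filter(..., pad_len = )`). Zero initial conditions are used for
every pass — the padding, not the initial state, handles transients. The
effective magnitude response of the zero-phase cascade is the *square* of
the single-pass response, which the test suite verifies on pure tones.

The recursion itself is implemented in C++ (via Rcpp): it is the innermost
loop of the whole pipeline, executed four times per channel per chunk.

### Band-power features

Each filtered 32-sample chunk is split into 4 contiguous 8-sample windows
(62.5 ms each; overlap is geometrically impossible since 4 × 62.5 ms fills
the chunk exactly). Each window is tapered with the symmetric Hamming
window, transformed with the 8-point DFT, and scaled to the two-sided
periodogram `pxx(k) = |X(k)|²/(Fs·L·U)` where `U` is the mean squared
window weight. All 8 two-sided bins are kept — no one-sided folding — the
bins are averaged across the 4 windows, each divided by 2π, and finally
averaged over bins to a single per-channel scalar.

Two scaling conventions deserve comment. First, the squared modulus is used
in the periodogram (the standard definition), not the plain modulus.
Second, the extra division by 2π is retained for fidelity to the original
processing chain even though it is a pure scale factor: band power enters a
linear classifier, so any fixed rescaling of all features is absorbed by
the weights (a property the tests check explicitly). With 8-point windows
at 128 Hz the bin spacing is 16 Hz, so no within-band bin selection is
possible or attempted — band limiting comes entirely from the preceding
filter.

### Two-stage logistic network

Network I separates the merged {thumb, index} class from fist; network II,
consulted only when fist is rejected, separates thumb from index. Each
network is a binary logistic model `P(class 1) = σ(Bᵀ[1, F])` with a
leading-1 intercept augmentation (the published form writes `Bᵀ·F` without
an explicit bias; an intercept is required for the model to be
location-invariant in feature space and is standard in every logistic
implementation).

The decision rule is class 1 iff `P > 0.5`. The source's printed rule
assigns "class 1" on both branches — an evident typographical slip — and is
resolved here in the only consistent way: class 2 otherwise. An exact tie
at `P = 0.5` (a measure-zero event) goes to class 2, simply because the
strict inequality belongs to class 1; the choice is documented rather than
important.

Training maximizes the ridge-penalized binomial log-likelihood by
iteratively reweighted least squares with step halving, to a gradient
max-norm below 1e−8 or at most 100 iterations; non-convergence raises a
warning and is flagged on the returned model, never silent. The default
ridge of 1e−8 (the convention of the Java data-mining tool used to fit the
original coefficients) exists for numerical conditioning on separable data,
not for regularization; at that size it does not measurably bias the
weights, and the suite checks the fit against an unpenalized
maximum-likelihood oracle. IRLS weights are floored at 1e−10 to keep the
Newton system finite under saturated probabilities.

The 75/25 train/test split helper is stratified by class with a fixed,
configurable seed; the original description is silent on both points, and
stratification is the only choice that keeps 31-per-class test sets exactly
balanced.

### Evaluation arithmetic

Per-class accuracy is recall — the confusion-matrix diagonal over its row
sum — expressed in percent and rounded *half away from zero* to integers.
That convention is pinned by the published tables themselves (20/31 → 65,
24/31 → 77); note one cell of those tables (16/31 = 51.6 %, printed 51 %)
is inconsistent with its own convention, and this package follows the
convention, not the cell. The mean accuracy is the unweighted (macro)
average of the three unrounded recalls, rounded last; with equal per-class
test counts macro and micro averaging coincide, so the distinction is
documented but observationally irrelevant here. Motor commands are emitted
as structured records (CSV trace), the desktop analogue of GPIO writes.

## The synthetic generator

No recordings from the original study are available, so the package ships a
generator (`synth_config()`, `generate_trial()`, `generate_dataset()`)
that produces data with precisely the statistical structure the pipeline
measures — and nothing more:

* per channel, a sum of sinusoids at 10 and 22 Hz (one Mu, one Beta
  component) with uniformly random phases, on top of white (default) or
  1/f Gaussian noise;
* class information only in the rhythm amplitudes: thumb raises F3, index
  raises FC5, fist raises both (`class_gain_map()`), matching the
  qualitative topography of sensorimotor decoding;
* optionally, eye-blink artifacts: half-sine lobes of 0.2–0.4 s and large
  amplitude added coherently to six frontal channels at Poisson event
  times — the "category I" high-blink-rate regime; the clean "category II"
  regime has none. The two shipped presets (`synth_preset()`, mirrored as
  YAML files under `inst/extdata/`) differ *only* in the blink parameters.

Reproducibility: one master seed plus a per-trial counter; the per-trial
RNG stream is seeded with `(seed · 100003 + counter) mod (2³¹ − 1)` and the
global RNG state is restored afterwards, so generation never perturbs a
caller's random stream.

### Calibration constants

The study conditions fix the acquisition geometry (14 channels, 128 Hz,
10 s trials, balanced classes) but give no quantitative effect sizes for
class differences or artifacts. The remaining generator defaults are
therefore calibration constants of this package, chosen once and clearly
not derived from any recording:

* `rhythm_amp = 6` µV per component and `noise_sigma = 14` µV — a
  realistic rhythm-to-background ratio for consumer hardware;
* `class_gain_map(specialist = 1.7, fist_gain = 2.3)` — set so the
  end-to-end pipeline on the clean preset lands in the mid-60s-to-high-70s
  per-class accuracy band that motivated the original design, rather than
  at ceiling or chance. The fist gain sits above the specialist gain so the
  three patterns stay linearly separable (sum of F3+FC5 band power
  separates fist; their difference separates thumb from index);
* `blink_amp = 400` µV at 0.6 events/s — large frontal lobes at a rate
  befitting a subject with habitual involuntary blinking.

### What the generator does and does not emulate

It reproduces: the trial geometry, class-dependent band-power contrasts at
the correct channels, broadband noise, and low-frequency frontal artifacts
that the 8 Hz high-pass mostly but not entirely removes. It does **not**
attempt: volume-conducted channel correlations, non-stationary rhythm
bursts (event-related desynchronization dynamics), 50/60 Hz mains
interference, electrode drift, or a forward head model. Passing tests
therefore demonstrate that the *pipeline* is correct and that it recovers
class structure of the kind the method assumes — they do not certify
performance on real EEG.

One consequence of the generator's simplicity is worth recording. Because
blink lobes are added coherently to six frontal channels, their residual
(after filtering) band-power contribution is essentially a rank-one
pattern across features, and a linear classifier *trained on contaminated
data* learns to cancel it — exactly as explicit EOG-regression artifact
removal would. Training and testing both on the blink regime consequently
shows no degradation. The regime comparison in the acceptance suite is
therefore run the way the original evaluation was: one network, fit on
clean-regime data (the original training pool was dominated by
clean-category subjects), then tested on each regime
(`pipeline_experiment(cfg, test_cfg = )`); under that protocol the blink
regime scores strictly lower on average across seeds.

## Problem sizes and runtime choices

The end-to-end experiments in the tests use 20 training trials per class
(800 training chunks per class) with 31 test chunks per class — the
embedded study's own test-set size — and 8 training trials per class for
the five-seed regime comparison. These sizes give stable accuracy
estimates while keeping the whole suite comfortably fast on a single CPU;
they are stated here so the reported bands can be reproduced exactly.

## Known limitations

* Only order-2 Butterworth sections are implemented; this is the pipeline's
  filter, not a general design toolbox.
* The classifier is the two-stage binary logistic network; no multinomial
  or alternative classifiers are provided.
* The 16 Hz bin spacing of the 8-point periodogram means the "band power"
  is broad-band by construction; finer spectral structure is invisible to
  the features, as in the original design.
* Synthetic accuracies characterize the implementation, not real-world
  decoding performance; the published accuracies on the original private
  recordings are reproducible only in their evaluation arithmetic, which
  the package recomputes from the published confusion matrices.
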
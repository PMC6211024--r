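---
title: "Deep normative modeling for wearable-sensor novelty detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep normative modeling for wearable-sensor novelty detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Wearable accelerometers make it cheap to record movement continuously, but
labeling the recordings — marking every freezing-of-gait episode in a
Parkinson's recording, or every bout of stereotypical rocking or hand
flapping in an autism study — is slow, subjective and expensive. Supervised
classifiers also inherit the severe class imbalance of such data (abnormal
movement is rare) and generalize poorly to movement types absent from the
training labels.

`normwear` takes the novelty-detection route instead: learn a model of
*normal* movement only, and score test windows by how far they deviate from
it. Deviation is quantified probabilistically, in three stages.

## The model

**1. A convolutional denoising autoencoder (DAE) learns normal movement.**
Recordings are segmented into fixed-length windows (1 s by default), each a
`w × c` array of `w` timesteps by `c` channels. A DAE
`f` is trained on corrupted versions of pure-normal windows to reproduce the
clean window, minimizing mean squared error with RMSprop. The encoder
alternates dropout, 1-D convolution, batch normalization, ReLU and pooling;
a fully-connected layer maps to a `q`-dimensional latent code; the decoder
mirrors the encoder with nearest-neighbour up-sampling in place of pooling
and a linear final convolution (accelerations are signed). A dropout layer
precedes every weight layer; at the input, that role is played by the
denoising corruption itself (zero-masking at the dropout rate plus additive
Gaussian noise, default sd 0.1 in standardized units).

**2. Monte-Carlo dropout turns the point reconstruction into a predictive
distribution.** Keeping dropout (and, by default, the input corruption)
active at test time and repeating the forward pass `m` times (default 50)
yields draws `f_i(x̃)`. Their per-feature empirical mean `M` and population
variance `V` (divisor `m`, as the mean of squared deviations) summarize the
predictive distribution. The normative probability map (NPM) is the
per-feature z-score

    Z = (X − M) / sqrt(max(V, floor))

i.e. the deviation of the observed window from its expected reconstruction
in units of predictive standard deviation. A variance floor (default 1e-6)
keeps the map finite. Some formulations write this ratio with the variance
itself in the denominator; since `V` is a variance and a z-score is a
deviation in standard-deviation units, the package divides by the standard
deviation and offers `denominator = "variance"` for the literal variance
form (rankings agree when `V` is roughly flat).

**3. Extreme-value statistics convert deviation maps into probabilities.**
Abnormal movement is treated as an *extreme* of the normal range, so each
window's map is reduced to a block-maxima summary: the trimmed mean of the
top 1% of `|Z|` (5% trimmed from each end of the top set; with the default
1-s windows `k = ceiling(0.01 p)` is small and trimming is skipped when it
would empty the set). A generalized extreme value distribution (GEVD) is
fitted by maximum likelihood to the summaries of held-out *normal* windows,
and its CDF evaluated at a test window's summary is that window's
abnormality probability. Because the CDF is monotone, rankings (hence AUC)
are identical to rankings by the raw summaries; the CDF supplies the
probability scale.

Two baselines ship alongside: *reconstruction-based* scoring, identical
except `Z = X − M` (no variance weighting); and a *one-class SVM* (RBF
kernel, `nu = 0.5`, `gamma = 1/q`) on the DAE's deterministic latent
encodings.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `window_seconds` | 1 | s | segment length; 32 samples at 32 Hz |
| `step_samples` | 10 | samples | sliding-window step |
| `abnormal_fraction_threshold` | 0.5 | fraction | window labeled abnormal at/above this fraction of abnormal timesteps |
| `training_purity` | 1 | fraction | training keeps only fully-normal windows |
| `dropout` (δ) | 0.1 | prob. | before every weight layer; also the input-masking rate |
| `gaussian_sd` | 0.1 | std. units | additive input corruption |
| `m` | 50 | draws | MC-dropout sample count |
| `top_fraction` / `trim_fraction` | 0.01 / 0.05 | fraction | block-maxima summary |
| `variance_floor` | 1e-6 | variance | caps z-scores where `V ≈ 0` |
| `reference_fraction` | 0.2 | fraction | normal training windows held out for the GEVD |

Architecture presets: `fog` (4 blocks, 32 filters, kernels 5/5/3/3, max
pooling) for short gait windows, and `smm` (3 blocks, 64 filters, kernels
9/5/3, average pooling, `q = 64`) for longer stereotypy windows. The per-layer widths are
package choices, sized so a full leave-one-subject-out experiment runs
comfortably on a single core; every element is configurable and none of
the package's validation depends on a specific width.

## Evaluation harness

`loso_experiment()` implements leave-one-subject-out cross-validation. For
each held-out subject: pure-normal windows of the remaining subjects are
pooled; a reference slice (20%, capped) is split off for the GEVD; a
per-channel standardizer and the DAE are fitted on the rest; every window
of the held-out subject is scored by each method; AUC (rank-based, ties
counted half) and AUPR (step-wise average precision, no interpolation) are
computed from the window labels. Subjects whose windows are single-class
are reported as skipped rather than silently dropped. Repetitions
re-randomize every stochastic stage (initialization, corruption, dropout,
MC draws) via `base_seed + repeat`; preprocessing is deterministic. No
held-out-subject window ever reaches training, standardization or GEVD
fitting — the returned `provenance` attribute records the subject sets per
fold so the guarantee is auditable.

`dropout_sweep()` repeats the experiment across dropout levels;
`aggregate_report()` produces per-subject and overall mean ± sd tables, the
overall row being the unweighted mean of per-subject means.

## The synthetic benchmark

`generate_dataset()` produces seeded multi-subject recordings: per subject,
a quasi-periodic gait signal (fundamental drawn from 1.5–2.5 Hz, three
decaying harmonics, per-channel random phases and amplitudes 0.6–1.4×),
additive Gaussian channel noise (sd 0.3 signal units), and annotated
anomaly episodes arriving as a Poisson process (durations 2–6 s) covering
an expected `anomaly_rate` (default 0.15) of the session. Tremor episodes
superimpose a 6–8 Hz oscillation at `anomaly_amplitude_factor` (default 2)
times the gait amplitude — a strong, spectrally distinct anomaly;
`gait_suppression` optionally attenuates stepping during episodes
(trembling-in-place), and stereotypy episodes replace gait with a 2–4 Hz
oscillation. A slow activity envelope and per-channel noise inflation
(optionally restricted to chosen subjects, emulating a degraded sensor) are
available. Subject effects, noise and episode placement use separate
substreams of the seed, so changing one facet leaves the others untouched.

Default problem sizes in the package's validation: 4 subjects × 300 s at
32 Hz (about 950 windows per subject), DAE trained for 5 epochs at batch
size 128 with learning rate 3e-3, which puts the detection AUC on its
plateau for this benchmark. The GEVD reference is capped at 400 windows,
ample for a 3-parameter ML fit. The dropout sweep trains longer
(15 epochs): higher dropout slows optimization, and an *undertrained*
network is exactly the failure mode of the z-scores described below.

### What the generator does and does not emulate

It reproduces the statistical skeleton the method relies on: subject-
specific quasi-periodic structure, channel correlations through shared
fundamentals, annotated rare episodes with distinct spectral content, and
controllable noise. It does not attempt biomechanical realism: no gravity
component, drift, saturation, posture changes, or non-stationary activity
mixtures of daily living. Passing the synthetic benchmark therefore shows
the pipeline is correct and the method behaves as designed under its own
assumptions — not that those AUC levels transfer to any clinical dataset.

### When variance weighting helps — and when it does not

Experiments with this package delineate the two regimes sharply.

*High-energy anomalies* (strong bursts superimposed on intact gait): plain
reconstruction error is an excellent detector, and the normative score
matches it closely but does not beat it. MC-dropout variance grows with
activation magnitude, so dividing by it slightly compresses exactly the
deviations one wants to keep.

*Low-energy anomalies* (stepping halts and only a faint tremor remains —
the freezing phenotype): reconstruction error tracks window energy, so
freezing windows score *below* vigorous normal walking and the
reconstruction baseline drops to near or below chance. The normative score
divides each deviation by the predictive standard deviation, which also
tracks energy, removing much of the confound; it stays clearly ahead of
reconstruction in every seed tried. This asymmetry — uncertainty weighting
as insurance against the energy confound — is the practical argument for
the normative route, and echoes what real freezing-of-gait benchmarks
show: reconstruction baselines sitting at or below chance for some
subjects while normative scoring stays informative.

Two limitations are worth stating plainly.

*MC-dropout variance is epistemic.* A channel whose noise floor is
chronically high gets confident (low-variance) conditional-mean
predictions and therefore *inflated* z-scores; the variance floor bounds
the numerics, but NPM does not automatically downweight statically noisy
channels the way a Gaussian-process predictive variance with a per-feature
noise term would. The original normative-modeling literature used exactly
such GP variances; the dropout approximation trades that aleatoric term
for scalability.

*The z-scores require an adequately trained network.* In an undertrained
autoencoder the MC variance on anomalous inputs scales with their energy
(the network partially passes the anomaly, and dropout noise rides on the
transmitted activations), so `V` can grow faster than the squared residual
and the z-scores *invert* — abnormal windows score below normal ones even
while raw reconstruction error separates them cleanly. With adequate
training the network projects inputs onto the normal-movement manifold,
the variance ratio between abnormal and normal windows falls back toward
one, and the z-scores behave. Diagnosing a suspect run is cheap: compare mean
`V` on the most deviant windows against the rest. This is also why the
evaluation harness varies only the network dropout in a sweep and keeps
the denoising corruption level fixed — corrupting more also means learning
less per epoch, which conflates the uncertainty estimator with training
adequacy.

## Numerical choices

- Convolutions are "same"-padded, stride 1, odd kernels; pooling floors
  odd lengths and the decoder's up-sampling repeats the last step when an
  odd length must be restored exactly.
- Batch normalization uses batch statistics during training (momentum 0.9
  running averages) and running statistics during MC sampling and
  deterministic inference.
- Inverted dropout (scale by `1/(1−δ)`) so inference needs no rescaling.
- The GEVD fit starts from probability-weighted-moment estimates and
  refines with Nelder–Mead on the negative log-likelihood (a Gumbel-ish
  restart guards against a stalled start); fewer than 30 reference
  summaries, or an (almost) constant sample, is an error.
- The GEV CDF is clamped to 0/1 outside its support, making it a total
  function; `|ξ| < 1e-12` switches to the Gumbel limit.
- Zero-variance channels in the standardizer are floored at 1e-8 with a
  warning; windows never span excluded-annotation gaps; a window is
  abnormal at `abnormal_fraction ≥ 0.5` (majority vote, the convention in
  the freezing-of-gait literature; the boundary counts as abnormal).
- Daphnet-style files are read with annotation semantics
  `0 = excluded, 1 = normal, 2 = abnormal`; excluded timesteps are dropped
  before windowing (they are neither normal nor abnormal, so neither
  training nor evaluation should see them).
- The high-pass step demeans exactly, then applies an order-2 Butterworth
  forward-backward; with a 0.1 Hz cutoff the edge transient spans roughly
  `1/cutoff` seconds at each end of a recording.
- Block-maxima summaries default to `|Z|` — movements can deviate in either
  sign, and the signed option is provided.
- The GEVD reference population is a held-out slice of the *training*
  normal windows, never the test subject: fitting the reference on test
  data would leak the test distribution into the score scale.

A corollary for the dropout-sensitivity sweep: the common observation that
the dropout level barely matters is an average over many subjects and
repetitions. At desk scale (a handful of folds, one repetition) the sweep
is stable under the registered test conditions, but across arbitrary seeds
an occasional high-dropout fold can hit the inversion pathology and widen
the spread — more averaging, or longer training, damps it.

## Known limitations

- AUC/AUPR levels reported on the synthetic benchmark say nothing
  quantitative about clinical data; external datasets require hours of
  training and are out of scope for the test suite.
- The DAE engine is plain R + BLAS with small C++ kernels; it is sized for
  1-second windows and a few thousand training windows, not for GPU-scale
  experiments.
- Supervised classification baselines and density-based latent-space
  novelty detection are deliberately absent.
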
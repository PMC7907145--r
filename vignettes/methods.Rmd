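---
title: "Topographic image sequence classification of multichannel EEG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Overview

`eegtopoclass` implements an end-to-end pipeline for two-class
classification of resting multichannel EEG:

1. **Preparation** — ocular channels removed, the recording cut into
   1400 ms trials (up to 55 per subject), each trial into six 400 ms
   windows stepped by 200 ms, and decomposed into theta (4–7 Hz), alpha
   (8–13 Hz) and beta (14–30 Hz) sub-bands.
2. **Features** — per window, channel and band, one scalar: either the
   fuzzy entropy of the band-filtered window, or the mean FFT amplitude
   over the band's DFT bins.
3. **Imaging** — electrode positions are flattened by the azimuthal
   equidistant projection and each channels-by-band frame is interpolated
   by the Clough–Tocher scheme onto a 32×32 mesh; theta, alpha and beta
   maps form the R, G and B channels of one image, six images per trial.
4. **Classification** — a time-distributed VGG-style CNN (configurations
   A–D) embeds each frame into 512 features; a single-layer LSTM reads the
   six embeddings; the last hidden state feeds a two-unit softmax. Trained
   with Adam (learning rate `1e-3`, moment decays 0.9/0.999), batch 32,
   dropout 0.5 on the fully connected layers, inside a tenfold
   cross-validation harness with a nested 8:1:1 train/validation/test
   split. RBF-SVM, KNN and L2 logistic regression serve as baselines on the
   flattened feature vectors.
5. **Group statistics** — channel-wise Welch t maps on subject-mean
   features with Benjamini–Hochberg and Bonferroni correction.

No clinical data ship with the package; a seeded synthetic cohort
generator supplies data with the statistical structure the method assumes.

# Fuzzy entropy

For a window $u(1),\dots,u(N)$ and embedding dimension $m$, the vectors
$X_i^m = \{u(i),\dots,u(i+m-1)\}$ are baseline-removed (each vector's own
mean $u_0(i)$ subtracted). The distance between two vectors is the
Chebyshev distance of the baseline-removed coordinates; the printed
source formula lacks the outer absolute value and can go negative, so the
standard Chen-style definition
$d_{ij} = \max_p |(u(i{+}p{-}1) - u_0(i)) - (u(j{+}p{-}1) - u_0(j))|$
is implemented. Similarity is the exponential fuzzy membership
$D_{ij} = \exp(-d_{ij}^{\,n}/r)$; $\Phi^m$ and $\Phi^{m+1}$ average the
memberships over the first $N-m$ vectors in both dimensions, and

$$\mathrm{FuzzyEn}(m, r, N) = \ln \Phi^m - \ln \Phi^{m+1}.$$

Defaults: $m = 2$, $r = 0.25\,\mathrm{SD}(u)$ (an absolute tolerance can
be supplied instead), and membership exponent $n = 2$ (the common
convention; the source leaves it unstated).

Numerical notes:

* A constant window (SD 0) returns 0 by convention; values in
  $(-10^{-9}, 0)$ from rounding are floored to 0.
* Membership terms with $d^n/r > 46$ (below $10^{-20}$) are dropped or
  clamped; their total effect on either $\Phi$ is bounded by $4\cdot10^{-16}$,
  orders of magnitude below the $10^{-10}$ oracle-equivalence tolerance the
  tests enforce. This also avoids a slow subnormal path in the system
  `exp`.
* The default $(m{=}2, n{=}2)$ path uses a vectorised degree-11 polynomial
  `exp` (relative error $\sim 10^{-13}$) with runtime CPU dispatch; the
  generic path uses the system `exp`. Both are compared against a literal
  brute-force implementation in the tests.
* FuzzyEn is exactly invariant under additive shifts. With the relative
  tolerance it is **not** scale-invariant for $n = 2$ (the exponent
  $d^2/r$ scales with the series scale); exact scale invariance holds for
  $n = 1$, and the property tests assert exactly that. This follows from
  taking the printed membership $\exp(-d^n/r)$ literally.

# Spectral features

`fft_spectrum()` computes $X(k) = \sum_n x(n) e^{-2\pi i nk/N}$ with the
radix-2 decimation-in-time butterfly when $N$ is a power of two and the
direct DFT sum otherwise. The pipeline's 400 ms window at 500 Hz gives
$N = 200$ — not a power of two — so the pipeline uses the direct path,
keeping bins at exact multiples of 2.5 Hz. The per-band scalar is the mean
of $|X(k)|$ over bins with $f_{lo} \le k f_s/N \le f_{hi}$, DC excluded
(the source does not state its per-band reduction; mean in-band amplitude
is this package's documented choice). At this resolution theta contains a
single bin (5 Hz) — documented, not an error. The bulk path evaluates only
the in-band DFT rows; tests verify it against the full-spectrum path.

# Band decomposition

The filter family is unspecified in the source; the package uses a
zero-phase (forward–backward) Butterworth band-pass, prototype order 4,
designed in zero/pole/gain form and applied as cascaded biquads with
odd-reflection padding and step steady-state initial conditions. The
design matches the reference `butter(4, [lo, hi], 'bandpass')` magnitude
response to the reference's own accuracy; at the narrow theta band the
zpk/SOS path is numerically cleaner than the transfer-function form.
Band filtering is applied per trial, before windowing, to keep filter
edge transients out of the windows.

# Topographic images

The azimuthal equidistant projection maps an electrode with polar angle
$\theta = \arccos z$ and azimuth $\phi$ to $(\theta\cos\phi,
\theta\sin\phi)$, so planar distance from the origin equals great-circle
distance from the head apex. A synthetic 10-10 style 60-channel template
supplies 3-D positions (midline row, 10% lateral ring, intermediate
electrodes by spherical interpolation); any montage can be supplied as
JSON.

Interpolation is the classic reduced Hsieh–Clough–Tocher macro-element:
each Delaunay triangle (incremental Bowyer–Watson with a deterministic
$10^{-9}$ jitter to break the exact co-circularities of symmetric caps) is
split at its centroid into three cubic Bézier patches; vertex values and
least-squares plane-fit gradients fix the outer control net, linearity of
the cross-edge normal derivative fixes the mid-edge interior points, and
C1 coupling across internal edges fixes the centre. The construction has
exact linear precision and interpolates the data, which the tests assert
at $10^{-6}$. Pixels outside the convex hull are 0. Because gradient
estimation and evaluation are both linear in the data, the whole map from
60 electrode values to 1024 pixels is precomputed once per montage as a
matrix, making bulk image generation a single matrix product.

Band order is theta→R, alpha→G, beta→B. Images are normalised per band by
min–max fitted on the training split only (degenerate band → all zeros;
held-out values clip to $[0,1]$).

**Classifier input transform.** Min–max alone leaves the between-trial
class contrast at a few percent of the pixel range on realistic feature
maps, which measurably stalls desk-scale training (the network spends
hundreds of Adam steps amplifying a tiny signal). The classifier therefore
applies the canonical Normalize step after the min–max map: each (pixel,
band) is standardised with mean/SD fitted on the training split of each
fold. Exported images stay in $[0,1]$; the standardisation belongs to the
model's input pipeline, exactly as in standard deep-learning image
workflows.

# The hybrid network

Configurations (3×3 kernels, stride 1, padding 1; 2×2/stride-2 max
pooling after each stack; sizes follow $y = (n + 2p - f)/s + 1$):

| config | stacks | flatten |
|---|---|---|
| A | 2×32 | 8192 |
| B | 2×32, 2×64 | 4096 |
| C | 2×32, 2×64, 1×128 | 2048 |
| D | 4×32, 2×64, 1×128 | 2048 |

FC-512 is part of the per-frame embedding, shared (time-distributed)
across the six frames; separate per-frame weights would multiply the
parameter count about six-fold. The LSTM is single-layer with hidden size
128 (unstated in the source; exposed as a parameter), gates
$f_t, i_t, \bar C_t, o_t$ on $[h_{t-1}, x_t]$, cell update
$C_t = C_{t-1} f_t + \bar C_t i_t$ and output $h_t = \tanh(C_t)\,o_t$
(the source prints "tan"; tanh is the universal definition). The head is
dropout → FC(2) → softmax. The printed parameter counts of the source
cannot be reconciled with any natural hidden size under these layers and
are not matched (its architecture is under-determined); the package's
counts are verified against closed-form layer sums instead.

The convolutional path runs in single precision (it dominates the FLOPs
and feeds BLAS sgemm); the LSTM and head run in double precision, so the
exposed LSTM step can be verified against a plain-R oracle at $10^{-6}$.
Backward passes are verified against finite differences. Training is
deterministic given the seed (single-threaded, private RNG for shuffling
and dropout).

# Cross-validation protocol

Trials are randomly partitioned into ten disjoint folds (trial-level by
default, mirroring random division of the segments; a subject-level
grouping option is provided for leakage-free evaluation). Within each
fold the remaining nine tenths split 8:1 into train/validation; weights
from the epoch with the highest validation accuracy are used on the test
fold, with early stopping once validation accuracy stops improving. The
reported accuracy is the mean over the ten test folds.

Desk-scale defaults train 30 epochs; the paper-scale 200 is available by
configuration. The acceptance experiment caps epochs at 3 for the effect
cohort and 1 for the null cohort — a pure time-budget scaling (one CPU,
~22 s/epoch at 640 training trials); learning rate, batch size and dropout
stay at their stated values.

# Synthetic cohort

Each channel of each 1400 ms trial is the sum of one oscillation per band
(frequency uniform within the band, phase uniform, amplitudes 0.7/1.0/0.5
for theta/alpha/beta) and 1/f pink noise of unit SD (spectral shaping of
seeded white noise). The patient class (label 1) additionally receives

* white noise with SD $= 3 \times$ `complexity_effect` $\times$ frontal
  weight — raising broadband irregularity, hence fuzzy entropy;
* theta amplitude multiplied by `theta_power_effect`^frontal weight.

The frontal weight is 1.0 for Fp/AF/F labels (incl. FT), 0.4 for FC/C/T,
0.1 posterior — the source reports frontal dominance but no generative
model. Every subject derives an independent RNG stream from the master
seed, so a cohort is a pure function of its configuration.

**Calibration.** The factor 3 in the noise SD is a one-time calibration:
the reference operating point (`complexity_effect = 0.8`) is specified to
reproduce the strongly separable per-trial regime of the source's real
cohort (classical baselines ≥ 0.9, hybrid DNN ≥ 0.9 under tenfold CV).
With a naive unit (gain 1), 0.8 yields a per-trial d′ of only ≈ 1, a
regime in which no classifier reaches the specified operating point at
desk scale. The calibration was fixed once and is not a claim about
schizophrenia physiology; the noise-mixing model is a stand-in.

**What the generator does not emulate.** Trials are drawn independently
given the class: there are no subject-specific fingerprints, no
artifacts (blinks, line noise), no medication effects, no non-stationarity
across a session. Consequently trial-level cross-validation is
leakage-free *on this synthetic world by construction* — a green
synthetic-recovery test validates the pipeline mechanics and the injected
effect's recoverability, and the null cohort guards against procedural
leakage (its tenfold accuracy must stay within binomial noise of 0.5). It
does **not** establish that trial-level splitting is unbiased on real EEG,
where subject fingerprints exist; use the subject-level CV option for
that question.

# Group statistics

Channel-level Welch (unequal-variance) t tests on per-subject mean
features — safer than the pooled form when group variances differ, which
the source leaves unstated. p values are two-tailed; significance flags
are provided for Benjamini–Hochberg FDR (step-up) and Bonferroni at
$\alpha = 0.05$. Statistics are computed at channel level on subject
means (not per pixel) to keep the test count interpretable; contrast maps
are rendered from channel statistics through the imaging module
($-\log_{10} p$). Between-group maps use independent-sample tests (the
source mentions paired tests only for within-subject condition
contrasts).

# Known limitations

* The synthetic world is far simpler than clinical EEG; headline
  accuracies on it say nothing about clinical performance.
* The direct-DFT bulk path is $O(N^2)$ per window; at $N = 200$ this is
  negligible, but very long windows would want a mixed-radix FFT.
* The SMO-based SVM is desk-scale (kernel matrix in memory, simplified
  working-pair selection); it is a baseline, not a production SVM.
* EDF support is a minimal 16-bit reader/writer (one data record),
  sufficient for round-tripping cohorts, not a general EDF(+)
  implementation.
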
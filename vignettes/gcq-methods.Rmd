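---
title: "Granger-causality quantification of EEG connectivity: methods and design"
author: "gcq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Granger-causality quantification of EEG connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcq)
```

## The problem and the model

Emotion recognition from EEG commonly works on the two-dimensional
valence–arousal model: each trial carries two self-assessment scores on a
1–9 scale, and cutting both axes at 4.5 ("low" strictly below, "high" at or
above) yields four quadrant classes — LALV, HALV, LAHV, HAHV. `gcq`
implements a connectivity-based recognizer whose single per-trial feature
summarizes the *directed* interactions between brain regions.

The causal primitive is pairwise Granger causality. For signals $x$ and $y$
and lag order $p$, two autoregressions are fit by ordinary least squares on
the common sample (the first $p$ points dropped):

$$y_t = a_0 + \sum_{i=1}^{p} a_i\, y_{t-i} + e_t
\qquad\text{(restricted)}$$

$$y_t = \tilde a_0 + \sum_{i=1}^{p} \tilde a_i\, y_{t-i}
      + \sum_{j=1}^{p} b_j\, x_{t-j} + \tilde e_t
\qquad\text{(unrestricted)}$$

$x$ Granger-causes $y$ to the extent that the second model predicts better,
measured by

$$F = \frac{(\mathrm{RSS}_r - \mathrm{RSS}_u)/p}
           {\mathrm{RSS}_u/(n_\mathrm{eff} - 2p - 1)},$$

which under the null follows $F(p,\, n_\mathrm{eff}-2p-1)$. The classical
binary verdict — "causal" when the unrestricted error variance is smaller
at the 5% level — is exposed on the fitted object (`$causal`), but the
pipeline works with the raw F-value itself: all $n(n-1)$ ordered pairs fill
a directed connectivity matrix (row = target, column = source; diagonal
stored as 0 and never thresholded), and the trial's scalar feature is the
**thresholded sum**

$$q = \sum_{i \ne j} F_{ij}\,\mathbf{1}[F_{ij} > \tau], \qquad \tau = 60
\text{ by default}.$$

A 6×6 matrix whose only suprathreshold cells are 101.54, 91.93 and 68.17
therefore quantifies to 261.64. The sum runs over the full directed matrix
(both triangles): the feature deliberately ignores orientation, which also
makes it invariant to the row/column convention.

## Pipeline order and stages

Per trial: band extraction → electrode combination (optional) →
normalization → Granger matrix → quantifier. The feature vector over all
trials is then itself min–max normalized before classification.

**Band extraction.** Channels are decomposed with a level-5 Daubechies
discrete wavelet transform and each rhythm is reconstructed from its
coefficient set only, giving a same-length time-domain signal (the Granger
stage needs time series, not coefficients). At 128 Hz the level-5 dyadic
components cover a5: 0–2, d5: 2–4, d4: 4–8, d3: 8–16, d2: 16–32,
d1: 32–64 Hz. The package maps bands to components *by their nominal
frequency ranges*: δ = {a5, d5} (0–4 Hz), θ = {d4} (4–8 Hz), α = {d3}
(8–16 Hz), β = {d2} (16–32 Hz), γ = {d1} (32–64 Hz). We chose the
range-faithful mapping because it is the one under which in-band test tones
actually reconstruct in their named band (a 20 Hz tone is a β signal, a
48 Hz tone a γ signal); the mapping is recomputed (with a message) for
other sampling rates. θ is implemented but excluded from
`default_bands()`: its F-values sit mostly below the operating threshold
and contribute nothing to the quantifier. The pass-through band `"all"`
skips decomposition entirely.

**Electrode combination.** The 32-channel montage is collapsed to six
bilateral areas — per hemisphere: frontal (5 channels),
central/temporal (4), parietal/occipital (5) — by the unweighted
arithmetic mean of member channels at every sample. The four midline
electrodes (Fz, Cz, Pz, Oz) lie on neither hemisphere; they are declared
*unassigned* in the reference montage, participate in 32-channel analyses,
and are excluded from area averages. `validate_montage()` enforces the
partition (sizes 5, 5, 4, 4, 5, 5, no overlap, no undeclared channel).
Averaging and wavelet reconstruction are both linear, so
decompose-then-combine equals combine-then-decompose; the cheaper order
(combine first: 6 instead of 32 decompositions) is therefore available as
a fast path and the equivalence is asserted in the test suite.

**Normalization.** Each signal is affinely mapped to $[-1, 1]$ with its
minimum at $-1$ and maximum at $+1$. A constant signal has no dynamic
range and is rejected with an explicit error. The Granger F-statistic is
provably invariant to affine rescaling of either input (asserted to 1e-8),
so normalization cannot change connectivity values; it is kept as a stage
because it fixes the scale of the *feature vector* fed to classifiers and
of any exported signals.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `wavelet_order` | 4 (db4) | Daubechies vanishing moments; band-dominance properties hold for orders 2–8 |
| `level` | 5 | decomposition depth; fixes the dyadic split at 128 Hz |
| `lags` | `"bic"` | per-pair lag choice in 1..`max_lag` minimizing the unrestricted model's BIC; any fixed integer for reproducible fast runs |
| `max_lag` | 20 | BIC search bound |
| `threshold` | 60 | F-value cut of the quantifier (strictly exceeded) |
| `K_range`, `kfold_range` | 1..20, 2..20 | classifier sweep grids |
| `snr_db` | 10 | synthetic sensor signal-to-noise ratio |

Lag selection deserves a note: "the optimal lag" is operationalized as the
BIC argmin of the unrestricted model, compared on a common sample (first
`max_lag` points dropped) and refit at the chosen order on the full
sample. Every connectivity matrix records the per-pair lag used
(`attr(m, "lag")`). Fixed-lag mode exists because BIC selection is the
dominant cost on long trials and a fixed small lag is often adequate for
screening runs.

## Classification and reporting

The feature is one-dimensional, so the classifiers are deliberately
simple. One-vs-all: each class in turn is the positive label against the
other three. Folds are stratified by class with a seeded shuffle —
positives are a minority (about a quarter), and unstratified folds can
easily lose all positives from a training split; a split that still ends
up single-class raises a "stratification error" naming fold and class.
Confusion counts are pooled over folds before computing metrics
(micro-averaging; per-fold macro-averaging is available by flag). Metrics
in percent: accuracy, sensitivity, and F1; an empty denominator yields
`NaN` with a warning rather than a silent 0.

KNN uses Euclidean distance on the scalar feature with two deterministic
tie rules: equidistant neighbours are taken in training-index order, and a
tied vote at even K goes to the positive class (the minority), which keeps
results byte-reproducible. SVM uses a radial kernel with `e1071` defaults
(linear available). The sweep reports, per classifier and class, the row
achieving maximum accuracy together with its K, k and the SE/F1 of that
same configuration; ties resolve toward the smallest k then smallest K, so
summaries are deterministic and re-derivable from the records.

## The synthetic generator

`generate_dataset()` emulates the shape of a standard 32-subject benchmark
recording: per subject, trials of 32 channels × 8064 samples at 128 Hz
(both configurable; the test suite and examples use 256–1024 samples to
keep runs in seconds-to-minutes on one CPU — the acceptance checks use
1024). Ground truth comes from a stationary VAR over six latent nodes, one
per brain area:

- **Coupling.** Each node has a self-lag of 0.5; class structure is graded
  directed lag-1 links: class 1 carries {1→3 (0.9), 3→5 (0.85),
  2→4 (0.8)}, class 2 {1→3 (0.65), 2→4 (0.6)}, class 3 {1→3 (0.5)},
  class 4 none. Strengths were sized once from the noncentrality
  relation $E[F] \approx n\,b^2\,\mathrm{var}(x)/\sigma^2$ so that every
  linked pair's expected F stays several-fold above the threshold of 60 at
  the shortest trial lengths used in examples, giving well-separated,
  class-ordered quantifiers (clear parameter recovery, not realism).
  Stationarity is enforced by rejecting any spec whose companion-matrix
  spectral radius reaches 1.
- **Mixing.** Every channel of an area carries its area's node plus
  independent white sensor noise at 10 dB SNR, so area averaging provably
  denoises toward the latent node; midline channels carry the node mean.
- **Band content.** Amplitude-modulated sinusoids at the band-center
  frequencies (2, 12, 24, 48 Hz) are added per node so band extraction has
  known energy targets. Each node's carrier is offset in frequency by
  1.5% per node and phase-randomized: identical deterministic carriers
  across nodes would be linearly cross-predictable and would fake causal
  links.
- **Seeding.** One master seed expands to per-trial child seeds through a
  documented multiplicative-counter scheme (`derive_seed(master, subject,
  trial)`), so any single trial is regenerable in isolation; all library
  randomness is scoped and restores the caller's RNG state.
- **Labels.** Scores are drawn uniformly inside each class's quadrant
  rectangle, kept 0.1 clear of the 4.5 boundary, so re-classification
  always recovers the generating class.

What the generator does *not* emulate: 1/f spectra, artifacts,
non-stationarity, volume conduction, or any dataset-specific effect
sizes — passing tests demonstrate that the pipeline recovers the
statistical structure the method assumes, not that any particular accuracy
transfers to real recordings. In particular the class coupling is
broadband: band-filtered runs of synthetic data exercise the mechanics but
concentrate class information in the pass-through band.

## Numerical choices

- **Wavelet boundaries.** The DWT uses periodized extension: it is exactly
  orthogonal, perfectly reconstructing (machine precision), and exactly
  linear, at the cost of wrap-around artifacts near the edges — which is
  why energy assertions exclude 64 boundary samples per side. Signals not
  a multiple of $2^{5}$ are padded by periodic recycling and trimmed back.
  Filter coefficients are generated by spectral factorization of the
  binomial half-band polynomial (minimum-phase root selection), matching
  published db2–db8 tables to 1e-12.
- **Degenerate inputs.** Constant signals: rejected by normalization
  ("zero dynamic range"); inside a connectivity matrix the affected cells
  become F = 0 with a warning instead of aborting the whole matrix, and
  the failure count travels on the result. Identical/collinear pairs:
  rank-deficiency of the unrestricted design is detected and reported.
  Trials failing feature extraction are dropped with their labels, with a
  warning naming the trial.
- **Determinism.** Identical configurations produce byte-identical
  artifacts; the pipeline writes its configuration verbatim alongside the
  outputs, plus a log of per-stage durations and Granger-fit counts (30
  per trial in 6-area mode against 992 in 32-channel mode — the whole
  point of electrode combination).

## Known limitations

- Pairwise (bivariate) Granger causality only — no conditional,
  multivariate, spectral, or cross-frequency variants; indirect links
  (1→3→5) can show as direct at sufficient sample sizes.
- Raw F-values are thresholded without multiple-testing correction across
  the matrix; the threshold (60) is an operating choice, configurable, and
  results are sensitive to it.
- The scalar quantifier discards all topology: two very different networks
  with equal suprathreshold mass are indistinguishable.
- Subject-independent evaluation only; no hyperparameter optimization
  beyond the reported grid sweep.
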
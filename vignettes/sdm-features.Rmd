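---
title: "Spatial dynamic-mode features: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial dynamic-mode features: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdmf)
```

## The model

A multichannel recording $x(t) \in \mathbb{R}^P$ sampled every $\Delta t$
seconds is modelled as one linear dynamical system,
$x_{l+1} = A x_l$, and the spectral decomposition of the best-fit $A$ is
estimated by exact dynamic mode decomposition (DMD). Each eigenpair
$(\varphi_k, \lambda_k)$ is an oscillatory component: a complex spatial
pattern $\varphi_k$ over channels, a frequency
$f_k = \arg(\lambda_k)/(2\pi\Delta t)$ in Hz, and a per-second amplitude
multiplier $r_k = |\lambda_k|^{1/\Delta t}$ ($r_k < 1$ decays, $r_k > 1$
grows). The signal is then approximately the superposition
$x(t) \approx \sum_{k=1}^{K} \varphi_k e^{\omega_k t} b_k$ with
$\omega_k = \ln(\lambda_k)/\Delta t$ and amplitudes
$b = \Phi^+ x(0)$.

Neural recordings have far more samples than channels, while exact DMD
assumes a tall snapshot matrix. The trial is therefore delay-embedded by
Hankel stacking: $h$ time-shifted copies are stacked so the snapshot
matrices are $hP \times (L-h)$, with $h$ the smallest integer satisfying
$h \ge (L+1)/(P+1)$ (`compute_h()`). Of each $hP$-dimensional stacked
mode, the first $P$ coordinates — the block aligned with the physical
channels — are kept as the spatial mode. We adopt this coordinate
reading (rather than "the first $P$ mode vectors") because the spatial
feature matrix below must be $P \times P$, indexed by channels; the
alternative reading cannot produce that shape. L2-normalization of the
modes is applied after the truncation to $P$ coordinates.

## From modes to decodable features

Two trials' mode matrices cannot be compared column-by-column (their
frequencies differ), so similarity is measured between the *subspaces*
they span with the Grassmann projection kernel
$k_p(\Phi^i, \Phi^j) = \|\Phi^{i\dagger}\Phi^j\|_F^2$. The identity
$k_p(\Phi^i, \Phi^j) = \mathrm{vec}(\Phi^i\Phi^{i\dagger})^\dagger
\mathrm{vec}(\Phi^j\Phi^{j\dagger})$ turns the kernel into an explicit
feature map: the real symmetric $P \times P$ matrix
$\Phi\Phi^\dagger$ (the *sDM features*), computable per trial with no
pairwise step. Its diagonal (snDM) measures per-channel energy in the
retained mode subspace; the strict upper triangle (seDM) measures
channel-pair co-participation. Because a linear model on the vectorized
sDM features optimizes the same problem as a kernel machine on the
projection-kernel Gram matrix, the two routes predict identically —
`nested_cv_classify()` supports both and the test suite asserts
label-for-label agreement.

Modes may also be grouped by the band containing $|f_k|$ before the
outer product (`band_filtered_sdm()`), using the eight conventional
bands 0–1, 1–4, 4–8, 8–13, 13–30, 30–80, 80–150, 150–500 Hz. Bands are
half-open $[low, high)$ with the final band closed — the edge
convention is ours, since only the edges themselves are conventional —
and conjugate pairs always share a band because assignment uses
$|f_k|$. An empty band yields an all-zero matrix, so band-filtered
features of fixed dimension always exist, and the band matrices sum
exactly to the unfiltered matrix. No per-band re-normalization is
applied: re-normalizing would destroy that additivity and silently
up-weight bands holding few modes.

## Tunable parameters

* **`rank` (K)** — the number of SVD components retained before the
  reduced operator is formed; the central hyperparameter. Too small
  misses dynamics, too large admits noise modes that dilute the snDM
  energies (on the bundled generator, accuracy degrades visibly above
  rank ~25 for 16 channels). The decoding harness treats rank as a
  grid-searched hyperparameter of the inner cross-validation;
  `default_rank_grid()` caps the conventional candidates
  {25, 50, 100, 200, 300} at the trial geometry's maximum.
* **`h`** — normally derived by `compute_h()`; override only for
  oracle-style comparisons (e.g. `h = 1` reduces to unstacked DMD).
* **Cost / lambda grids** — `default_cost_grid()` is $10^{-1}..10^8$
  for the SVM/logistic cost; `default_lambda_grid()` is
  $10^{-8}..10^8$ (17 candidates) for ridge, selected per target
  dimension by inner-CV mean squared error. For the L1-regularized
  logistic route (glmnet) the cost is mapped to the penalty as
  $\lambda = 1/(nC)$, so the same grid semantics apply.
* **CV scheme** — the full protocol is 10-fold outer CV repeated 10
  times with 10-fold inner CV repeated 10 times, stratified so per-fold
  class imbalance is minimal; imbalanced training folds are corrected by
  deterministic cyclic oversampling up to the majority count.
  Classification is scored by balanced accuracy (mean per-class
  recall); regression by Pearson correlations Fisher z-transformed and
  averaged over folds, then dimensions.

## Numerical choices

* Singular values below $\max(hP, L-h)\cdot\varepsilon\cdot s_1$ are
  discarded before $S^{-1}$ is formed, preventing blow-up when the
  requested rank exceeds the numerical rank; the effective rank is
  reported. A numerically zero matrix raises an error.
* Modes are returned in a canonical order — ascending $|f_k|$, ties
  broken by the sign of $f_k$ then descending $|b_k|$ — so results are
  reproducible across eigensolver implementations, which impose no
  order of their own.
* Eigenvalues with $|\lambda| \approx 0$ ("dead" modes, no
  continuous-time representation) are dropped with a warning.
* Amplitudes are fitted on the stacked state, $b = \tilde\Phi^+
  \tilde{x}(0)$, because the $P$-row truncated modes are not a basis
  for the stacked dynamics.
* $\Phi\Phi^\dagger$ is checked to be real up to a relative imaginary
  residue of $10^{-8}$ (configurable); a larger residue means the mode
  set lost a conjugate partner and is an error rather than something to
  silently discard.
* Fisher z-transforms clip $|r|$ at $1 - 10^{-12}$ so perfectly
  correlated pairs remain finite.
* Inner-CV grid ties resolve to the first candidate in grid order
  (smallest rank, then smallest cost), a deterministic and mildly
  regularizing convention.

## The synthetic generator

`make_two_component_signal()` reproduces the analytic two-component example —
a 13 Hz sine decaying as $0.25^t$ with spatial profile
$\mathrm{sech}(p+3)$ plus an 8 Hz sine growing as $2^t$ with profile
$\mathrm{sech}(p-3)$, on 81 positions at 1 kHz for 0.5 s. It is the
package's exactness witness: stacking gives $h = 7$ and 493 SVD
components, exactly 4 nonzero singular values survive, and rank-4 DMD
returns conjugate pairs at $|f| = 13$ Hz with $r = 0.25$ and
$|f| = 8$ Hz with $r = 2$.

`make_trial_set()` emulates the structure the method targets in ECoG
decoding: every class shares a 10 Hz background oscillation with a
broad spatial footprint, and a 100 Hz component rides on a
class-specific sech-shaped channel subset, with fresh uniform phases
per trial and white Gaussian noise. The defaults — 3 classes × 40
trials, 16 channels, 500 samples at 1 kHz, unit-amplitude oscillators,
noise sd 0.2 — were fixed once as a compact regime with clear spatial
class structure at a signal-to-noise ratio typical of band-limited
cortical oscillations over broadband background. sech profiles are kept
as the canonical spatial family to match the worked example.

What the generator deliberately does *not* emulate: 1/f background
spectra, line noise and harmonics, volume conduction, channel-specific
noise, artifacts, or non-stationarity across trials. Passing tests
therefore certify the algebra and the harness — kernel/feature-map
equivalence, band additivity, parameter recovery, leak-free nested CV —
not decoding performance on clinical recordings.

## Problem sizes used in the checks

The automated checks run the full pipeline at reduced sizes chosen for
quick iteration: the 120-trial default generator set, 5-fold outer ×
1 repeat and 3-fold inner × 1 repeat cross-validation, rank candidates
{4, 16} and cost grids of 2–3 points. The full-scale protocol
(10×10-fold nested CV, full grids) is the package default and is what
`cv_scheme()` produces when called without arguments.

## Degenerate inputs and edge behavior

Constant signals decompose as rank 1 with $\lambda = 1$ ($f = 0$,
$r = 1$). Zero-norm modes are dropped with a warning at normalization.
Reconstruction refuses time horizons where growing modes overflow.
Trials longer than the 512-point FFT window are rejected by the
single-window PSD rather than silently Welch-averaged. A training fold
that loses a class entirely aborts the fit rather than scoring a
degenerate model; stratified folds make this unreachable for the
bundled generators.

## Known limitations

* Exact DMD with hard SVD truncation only; no total-least-squares,
  optimized, or multi-trial joint variants.
* One linear system per trial: within-trial non-stationarity is folded
  into growing/decaying modes rather than modelled.
* The projection kernel ignores the eigenvalues; two trials with
  identical spatial subspaces but different frequencies are
  indistinguishable to the unfiltered sDM features (the band-filtered
  variant partially restores that information).
* Persistence is plain-text CSV/JSON; no EDF/BrainVision readers are
  bundled (the trial-set reader is the documented adapter point).
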
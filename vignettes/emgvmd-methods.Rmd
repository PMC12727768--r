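---
title: "Methods: spectro-temporal sEMG features by variational mode decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectro-temporal sEMG features by variational mode decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgvmd)
```

## The problem

Myoelectric control systems classify hand and wrist motions from surface
EMG. The signal is non-stationary and broadband: a contraction modulates
both the amplitude envelope and the spectral content of each channel.
Classical window-level descriptors (mean absolute value, zero crossings,
waveform length, RMS and relatives) summarize amplitude structure only.
`emgvmd` implements a spectro-temporal feature pipeline — variational mode
decomposition followed by per-segment singular-value reduction — together
with an EMD-based baseline, the classical time-domain sets, and a
cross-validated benchmark harness, all testable end to end on synthetic
recordings.

## Variational mode decomposition

VMD represents a signal $s$ as $K$ band-limited AM-FM modes
$u_n(t) = b_n(t)\cos\theta_n(t)$ with center frequencies $\omega_n$,
chosen to minimize the summed bandwidths

$$\min_{\{u_n\},\{\omega_n\}} \sum_n \left\| \partial_t\!\left[
\left(\delta(t) + \tfrac{j}{\pi t}\right) * u_n(t)\right]
e^{-j\omega_n t} \right\|_2^2
\quad \text{s.t.} \quad \sum_n u_n = s .$$

The bandwidth of a mode is the squared $H^1$ seminorm of its Hilbert
analytic signal demodulated to baseband. The constraint is relaxed with a
quadratic penalty $\alpha$ and a Lagrange multiplier $\lambda$, and the
augmented Lagrangian is minimized by ADMM entirely in the frequency
domain. Each sweep performs, per mode, the Wiener-filter update

$$\hat u_n(\omega) \leftarrow
\frac{\hat f(\omega) - \sum_{i\neq n}\hat u_i(\omega)
      + \hat\lambda(\omega)/2}
     {1 + 2\alpha\,(\omega - \omega_n)^2},$$

re-estimates $\omega_n$ as the power centroid
$\int_0^\infty \omega\,|\hat u_n|^2 d\omega \big/
 \int_0^\infty |\hat u_n|^2 d\omega$, and (when the dual step $\tau > 0$)
performs dual ascent $\hat\lambda \leftarrow \hat\lambda +
\tau(\hat f - \sum_n \hat u_n)$. Modes are updated sequentially
(Gauss–Seidel), which breaks ties between identically initialized modes.

### Numerical choices

* **One-sided spectra.** All updates operate on the non-negative frequency
  half ($\omega \in [0, 0.5)$ cycles/sample); the time-domain modes are
  recovered by Hermitian completion and inverse FFT, so they are exactly
  real.
* **Boundary handling.** The signal is mirror-extended by half its length
  at each end before the FFT and cropped after inversion, which suppresses
  edge ringing; odd lengths are first padded with one edge-replicated
  sample.
* **Convergence.** Iteration stops when
  $\sum_n \|\hat u_n^{k+1}-\hat u_n^k\|^2 / \|\hat u_n^k\|^2 <$ `tol`
  (default $10^{-7}$) or after `max_iter` (default 500) sweeps.
* **Degenerate modes.** An all-zero mode spectrum has no power centroid;
  the update reports this and the mode keeps its previous center
  frequency. An all-zero input returns all-zero modes with reconstruction
  error 0.
* **Ordering.** Modes are always returned in ascending center-frequency
  order, so feature columns are comparable across runs.

### Initialization: why spectral peaks

Center-frequency initialization is genuinely open. We evaluated the
common schemes on a noisy tri-harmonic signal
($10/60/200$ Hz tones, amplitudes $1/0.5/0.25$, Gaussian noise
$\sigma = 0.1$, $f_s = 1000$ Hz): with uniform or zero initialization a
mode frequently locks onto an empty spectral region — its Wiener-weighted
power centroid sees locally flat noise and stops moving — and recovery
fails for most noise realizations (center-frequency errors of 100–200 Hz).
The failure is a property of the fixed-point iteration, not of this
implementation. The default is therefore `init = "peaks"`: the $K$
largest periodogram bins, taken greedily while masking one Wiener
half-bandwidth $1/\sqrt{2\alpha}$ around each pick, with uniform filling
if the spectrum runs out of distinct peaks. With peak initialization the
same noisy signal is recovered to well under 0.1 Hz for every seed we
probed. Uniform, zero and seeded-random schemes remain available in the
`init` argument.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `K` | — | number of modes; feature dimensionality is channels × K |
| `alpha` | 2000 | bandwidth penalty (dimensionless); each mode's Wiener half-width is $\approx 1/\sqrt{2\alpha}$ cycles/sample |
| `tau` | 0 | dual-ascent step; 0 = pure penalty method (noise tolerant), $>0$ enforces near-exact reconstruction on clean signals |
| `tol` | 1e-7 | relative spectral-change stopping threshold |
| `dc` | FALSE | pin $\omega_1 = 0$ to capture a DC/trend mode |

With `tau = 0` the summed modes reconstruct only the in-band part of the
signal; reconstruction error $\le 10^{-2}$ is reached with `tau = 1` when
the input's band can actually be covered by the $K$-mode bank (total
coverage $\approx 2K/\sqrt{2\alpha}$ cycles/sample) — asking 4 modes at
$\alpha = 2000$ to reproduce broadband noise is ill-posed by design, not a
solver failure.

## Empirical mode decomposition (baseline)

EMD extracts intrinsic mode functions by sifting: cubic splines through
the local maxima and minima form upper/lower envelopes, their midline is
subtracted, and the process repeats until the candidate is a valid IMF.
Each accepted IMF is subtracted from the running residue, so
$f(t) = \sum_i h_i(t) + r(t)$ holds to machine precision by construction.
Choices the method leaves open:

* **Stopping.** A sift is accepted when the Cauchy criterion
  $\sum(p_{\text{prev}}-p)^2 / \sum p_{\text{prev}}^2 < 0.2$ holds *and*
  the candidate satisfies the IMF property (extrema and zero-crossing
  counts differ by at most one), capped at 100 sifts per IMF. The combined
  rule is needed: the Cauchy criterion alone accepts noise IMFs that
  violate the extrema property.
* **Extrema.** Strict sign changes of the first difference; plateaus
  count once, at their midpoint. Envelope splines mirror two extrema
  beyond each end to tame end swings.
* **Termination.** Decomposition stops when the residue has fewer than
  two maxima or two minima (monotonic or single-hump residues), or at
  `max_imfs`.

## Feature construction

Every mode (VMF or IMF) of every channel is segmented with a 250 ms
window and 10 % overlap (500-sample windows, 450-sample hop at 2000 Hz; a
trailing partial window is dropped; count $= \lfloor (T-w)/\text{step}
\rfloor + 1$). Each windowed segment, viewed as a $1 \times L$ matrix, has
a single singular value — its Euclidean norm — which is the feature. The
singular values of $X$ are the square roots of the eigenvalues of $X^TX$;
the package exposes both the general `svd_singular_values()` and the
segment reduction. A `shape = "reshape"` alternative folds the segment
into an $r \times c$ matrix ($r = \lfloor\sqrt L\rfloor$) and uses the
leading singular value; the vector-norm default is what produces the
channels × modes dimensionality the feature matrix is built around.

EMD yields a data-dependent number of IMFs, so the EMD-SVD set fixes
`n_imfs` columns per channel (default 8) and zero-fills the missing ones —
matrix shape must be stable across trials for cross-validation.

The time-domain sets are computed per segment and channel: TD8 = (MAV,
ZC, WL, RMS, SE, STD, VAR, SNR), where formulas the literature leaves
open are fixed as SE = STD/$\sqrt n$ (standard error) and SNR = MAV/STD
(0 for a constant segment); LS4 = (MFL, MSR, WAMP, L-scale) and LS9 =
(LS, MAV, ZC, SSC, WL, RMS, IAV, DASDV, VAR), with the L-scale estimated
by the unbiased second-L-moment formula. Thresholds default to
`wamp_threshold = 0.05` signal units and `zc_threshold = 0`, both
exposed. Segment labels use the majority rule: a window keeps a class
only if more than half its samples carry it; boundary-straddling windows
are dropped; rest (label 0) is excluded from classification by default.

## Synthetic recordings

`make_synthetic_emg()` emulates a gesture-acquisition protocol — by
default 3 channels at 2000 Hz, 4 motion classes, 8 repetitions of 5-s
contractions separated by 5-s rests — with each contraction modeled as
band-limited Gaussian noise (class- and channel-specific center,
bandwidth and gain) under a trapezoidal envelope with 10 % ramps, over a
low-amplitude broadband baseline; all randomness flows from one seed.
This surrogate captures exactly the two properties the features exploit:
amplitude modulation and class-distinct spectral coloring. It does *not*
model motor-unit action-potential trains, electrode lift-off, fatigue
drift, cross-talk or amputee-specific signal statistics, so passing tests
demonstrate the pipeline's correctness and discriminative mechanics, not
clinical-grade accuracy on recorded data.

## Evaluation harness

Cross-validation is stratified 10-fold (per-class remainders are dealt to
the currently smallest folds, keeping fold sizes within one of each
other; classes smaller than $k$ trigger an unstratified fallback with a
warning). Features are z-scored with statistics fit on the training folds
only. Classifier backends are the standard R implementations: SVM with a
Gaussian kernel and box constraint 1 (`e1071`), KNN with K selected by
inner cross-validation over $\{1,3,5,7,9,11\}$ on the training folds
(`class`), a decision tree with a small deterministic depth/min-split
grid chosen by inner CV (`rpart` — a fixed grid rather than a Bayesian
optimizer, for reproducibility), and a random forest with 146 trees
(`randomForest`). Accuracy is the confusion-matrix trace over the total;
the coefficient of variation (sd/mean × 100) summarizes the spread of
per-subject accuracies. `vmf_sweep()` regenerates features from the raw
signal for each mode count and reports $M$ = channels × K per row;
extraction wall time is reported but never asserted.

## Problem sizes

The test-suite and acceptance computations run on reduced-scale sessions
chosen to exercise every code path while keeping a laptop run pleasant: 2
repetitions of 2-s contractions with 2-s rests (32 s, 64 000 samples, ~70
active segments) for the end-to-end benchmark, 1-s blocks for
dimensionality checks, and 1-s signals at 1000 Hz for the decomposition
oracles. These sizes are the package's validation choices; the defaults
of `protocol_spec()` remain the full 8 × 5 s protocol.

## Known limitations

* VMD requires choosing `K`; the package sweeps it but does not select it
  adaptively, and multivariate (joint multi-channel) VMD is out of scope.
* With `tau = 0` the decomposition is deliberately lossy outside the
  modes' bands; reported reconstruction errors reflect that.
* The EMD baseline inherits EMD's mode mixing and noise sensitivity —
  that contrast is the point of the benchmark.
* Synthetic separability is an upper bound: spectrally overlapping
  classes, non-stationary fatigue effects and real electrode artifacts
  will lower accuracies in ways the generator does not model.
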
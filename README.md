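# emgvmd

Spectro-temporal feature extraction and benchmarking for myoelectric
pattern recognition from multi-channel surface electromyography (sEMG).

Prosthesis and rehabilitation controllers classify hand/wrist motions from
windowed sEMG features. Classical time-domain descriptors (MAV, ZC, WL,
RMS, ...) capture only amplitude structure; `emgvmd` implements a
spectro-temporal alternative: each channel is decomposed into `K`
band-limited modes by **Variational Mode Decomposition (VMD)**, every mode
is cut into overlapping 250 ms windows, and each windowed mode segment is
reduced to a single **singular value**, yielding an `N x (channels * K)`
feature matrix (`N` = number of segments). The package also provides the
EMD-based analogue and classical time-domain sets as baselines, a
protocol-faithful synthetic sEMG generator, and a stratified 10-fold
cross-validation harness with SVM, KNN, decision-tree and random-forest
backends.

## The model

VMD decomposes a signal *s* into modes *u_n* with center frequencies
*w_n* by solving

```
min_{u_n, w_n}  sum_n || d/dt [ (delta(t) + j/(pi t)) * u_n(t) ] e^{-j w_n t} ||_2^2
subject to      sum_n u_n = s
```

i.e. it minimizes the summed baseband bandwidths of the modes' analytic
signals subject to reconstruction. The augmented Lagrangian (quadratic
penalty `alpha`, multiplier `lambda`) is solved by ADMM in the frequency
domain: each mode update is the Wiener filter

```
u_n(w)  <-  ( f(w) - sum_{i != n} u_i(w) + lambda(w)/2 ) / ( 1 + 2 alpha (w - w_n)^2 )
```

and each center frequency is re-estimated as the power centroid
`w_n <- Int w |u_n(w)|^2 dw / Int |u_n(w)|^2 dw`. For a windowed segment
treated as a `1 x L` matrix the single singular value of `X = U S V^T`
equals its Euclidean norm, which is the per-segment feature.

## Worked example

```r
library(emgvmd)

# 1. simulate a reduced acquisition session: 4 motions, 3 channels,
#    2 repetitions of 2-s contractions with 2-s rests at 2000 Hz
rec <- make_synthetic_emg(protocol_spec(n_reps = 2, contraction_s = 2,
                                        rest_s = 2, seed = 11))
rec
#> <emg_recording> 3 channel(s) x 64000 samples @ 2000 Hz (32.00 s)
#>   labels: 0:32000 1:8000 2:8000 3:8000 4:8000

# 2. preprocess: 10-450 Hz band-pass, 50 Hz notch
rec <- notch_filter(bandpass_filter(rec))

# 3. spectro-temporal features: 6 modes/channel, 250 ms / 10% windows
fv <- extract_vmd_svd(rec, K = 6)
fv
#> <feature_matrix> VMD_SVD: 140 segment(s) x 18 feature(s), 5 class(es)

# 4. benchmark against the classical time-domain set
cross_validate(fv, "rf", seed = 3)
#> <cv_result> rf, 10-fold: accuracy 98.6% +/- 4.5%
cross_validate(extract_td(rec, "TD8"), "rf", seed = 3)
#> <cv_result> rf, 10-fold: accuracy 100.0% +/- 0.0%
```

The recording holds 32 s of labeled signal (label 0 = rest, excluded from
classification). The 18 feature columns are `3 channels x 6 modes`; each
row is one 500-sample window. On this synthetic session with
well-separated class spectra both feature sets are near-ceiling; the
VMD-SVD set carries the spectral structure that time-domain features
cannot see, which matters as classes become spectrally similar.

A command-line front end wrapping the same functions is installed as
`exec/emgvmd` (subcommands `simulate`, `decompose`, `extract`, `classify`,
`sweep`; run it without arguments for usage).

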
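# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# single-channel recording holding a pure tone
tone_recording <- function(freq, fs = 2000, n = 10000, amp = 1) {
  t <- (seq_len(n) - 1) / fs
  emg_recording(matrix(amp * cos(2 * pi * freq * t), nrow = 1), fs)
}

# steady-state amplitude of a filtered unit tone (middle 40% of samples)
steady_amplitude <- function(x) {
  n <- length(x)
  max(abs(x[floor(0.3 * n):ceiling(0.7 * n)]))
}

# zero-phase magnitude response of an Arma filter at frequency f (Hz):
# single-pass |H| squared by the forward-backward application
filtfilt_gain <- function(filt, f, fs) {
  h <- signal::freqz(filt$b, filt$a, Fs = fs,
                     W = seq(0, fs / 2, length.out = 4096))
  stats::approx(h$f, Mod(h$h), xout = f)$y^2
}

# reduced-scale synthetic session: 4 motions, 3 channels, 2 reps of 2-s
# contractions with 2-s rests at 2000 Hz (seed fixed for the suite)
pipeline_recording <- function() fixture("pipeline_rec", function() {
  rec <- make_synthetic_emg(
    protocol_spec(n_reps = 2, contraction_s = 2, rest_s = 2, seed = 11))
  notch_filter(bandpass_filter(rec))
})

pipeline_vmd_features <- function() fixture("pipeline_vmd", function() {
  extract_vmd_svd(pipeline_recording(), K = 6)
})

pipeline_td_features <- function() fixture("pipeline_td", function() {
  extract_td(pipeline_recording(), "TD8")
})

# short session for dimensionality checks (1 rep, 1-s contractions)
short_recording <- function() fixture("short_rec", function() {
  make_synthetic_emg(
    protocol_spec(n_reps = 1, contraction_s = 1, rest_s = 1, seed = 21))
})
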
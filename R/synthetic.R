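#' Tri-harmonic test signal
#'
#' Sum of three cosines plus optional white Gaussian noise — the classic
#' benchmark for checking that a mode decomposition separates well-spaced
#' tones and stays robust under noise.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s duration in seconds.
#' @param freqs three distinct frequencies in Hz, all below `fs/2`
#'   (default 10, 60, 200).
#' @param amps three amplitudes (default 1, 0.5, 0.25).
#' @param noise_sigma standard deviation of added Gaussian noise
#'   (default 0).
#' @param seed RNG seed for the noise.
#' @return Numeric vector of `fs * duration_s` samples.
#' @export
make_triharmonic <- function(fs, duration_s, freqs = c(10, 60, 200),
                             amps = c(1, 0.5, 0.25), noise_sigma = 0,
                             seed = 0L) {
  stopifnot(length(freqs) == 3, length(amps) == 3)
  if (any(freqs >= fs / 2)) stop("frequencies must be below Nyquist (fs/2)")
  if (anyDuplicated(freqs)) stop("frequencies must be distinct")
  n <- round(fs * duration_s)
  t <- (seq_len(n) - 1) / fs
  x <- amps[1] * cos(2 * pi * freqs[1] * t) +
       amps[2] * cos(2 * pi * freqs[2] * t) +
       amps[3] * cos(2 * pi * freqs[3] * t)
  if (noise_sigma > 0)
    x <- x + with_seed(seed, stats::rnorm(n, sd = noise_sigma))
  x
}

#' Spectral profile of one motion class
#'
#' Describes how a motion class colors each channel: a per-channel band
#' center and bandwidth for the band-limited noise carrier, and a
#' per-channel gain. Distinct centers/gains across classes make classes
#' separable; identical profiles make them indistinguishable.
#'
#' @param class_id integer class label (>= 1; 0 is reserved for rest).
#' @param band_centers per-channel band centers in Hz, inside (10, 450).
#' @param bandwidths per-channel bandwidths in Hz.
#' @param gains per-channel positive amplitude scalars.
#' @return A list of class `motion_profile`.
#' @export
motion_profile <- function(class_id, band_centers, bandwidths, gains) {
  stopifnot(class_id >= 1, all(gains > 0),
            all(band_centers > 10), all(band_centers < 450),
            length(bandwidths) == length(band_centers),
            length(gains) == length(band_centers))
  structure(list(class_id = as.integer(class_id),
                 band_centers = band_centers, bandwidths = bandwidths,
                 gains = gains),
            class = "motion_profile")
}

#' Default well-separated motion profiles
#'
#' Convenience set of `n_motions` profiles with band centers spread over
#' 50-350 Hz and per-channel gain patterns rotated across classes, giving
#' strongly separable synthetic classes.
#'
#' @param n_motions number of classes.
#' @param n_channels number of channels.
#' @param bandwidth common bandwidth in Hz (default 40).
#' @return List of [motion_profile()] objects.
#' @export
default_motion_profiles <- function(n_motions, n_channels, bandwidth = 40) {
  centers <- seq(50, 350, length.out = n_motions)
  lapply(seq_len(n_motions), function(k) {
    g <- 0.5 + 1.5 * ((seq_len(n_channels) + k) %% n_channels) /
      max(1, n_channels - 1)
    motion_profile(k,
                   band_centers = rep(centers[k], n_channels),
                   bandwidths = rep(bandwidth, n_channels),
                   gains = g)
  })
}

#' Acquisition protocol for synthetic sEMG
#'
#' Mirrors a typical gesture-recording session: `n_reps` repetitions of
#' each of `n_motions` contractions, each held `contraction_s` seconds and
#' separated by `rest_s` seconds of rest, recorded on `n_channels` channels
#' at `fs` Hz. Defaults follow a 3-channel, 2000 Hz, 4-motion protocol with
#' eight 5-s contractions and 5-s rests.
#'
#' @param n_channels number of channels (default 3).
#' @param fs sampling rate in Hz (default 2000).
#' @param n_motions number of motion classes (default 4).
#' @param n_reps repetitions per motion (default 8).
#' @param contraction_s contraction duration in seconds (default 5).
#' @param rest_s rest duration in seconds (default 5).
#' @param envelope_ramp trapezoid onset/offset ramp as a fraction of the
#'   contraction (default 0.1).
#' @param noise_sigma baseline broadband noise s.d., also the rest-period
#'   amplitude (default 0.02).
#' @param seed master RNG seed; all randomness in the generator flows from
#'   it.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(n_channels = 3, fs = 2000, n_motions = 4,
                          n_reps = 8, contraction_s = 5, rest_s = 5,
                          envelope_ramp = 0.1, noise_sigma = 0.02,
                          seed = 1L) {
  stopifnot(n_channels >= 1, fs > 0, n_motions >= 1, n_reps >= 1,
            contraction_s > 0, rest_s > 0,
            envelope_ramp >= 0, envelope_ramp <= 0.5, noise_sigma >= 0)
  structure(as.list(environment()), class = "protocol_spec")
}

# trapezoid: ramp up over `ramp` fraction, hold, ramp down
trapezoid_envelope <- function(n, ramp) {
  r <- max(1L, round(n * ramp))
  env <- rep(1, n)
  env[seq_len(r)] <- seq(0, 1, length.out = r)
  env[(n - r + 1L):n] <- seq(1, 0, length.out = r)
  env
}

# zero-phase band-pass shaped Gaussian noise
bandlimited_noise <- function(n, fs, center, bw, pad = 200L) {
  lo <- max(1, center - bw / 2)
  hi <- min(fs / 2 - 1, center + bw / 2)
  filt <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  w <- stats::rnorm(n + 2L * pad)
  y <- signal::filtfilt(filt, w)[(pad + 1L):(pad + n)]
  # renormalize so the carrier has unit variance before gain scaling
  y / stats::sd(y)
}

#' Generate a synthetic multi-channel sEMG recording
#'
#' Emulates a gesture-acquisition session: for every repetition of every
#' motion, each channel carries Gaussian noise band-pass shaped to that
#' class's per-channel (center, bandwidth), scaled by the channel gain and
#' multiplied by a trapezoidal contraction envelope; rest periods carry
#' low-amplitude broadband noise. Per-sample labels are attached (rest =
#' 0). Repetitions are interleaved motion-by-motion (m1 r1, m2 r1, ...,
#' m1 r2, ...), each followed by a rest.
#'
#' @param protocol a [protocol_spec()].
#' @param profiles list of [motion_profile()]s, one per motion class; by
#'   default [default_motion_profiles()] for the protocol.
#' @return An [emg_recording()] with labels.
#' @examples
#' rec <- make_synthetic_emg(protocol_spec(n_reps = 1, contraction_s = 1,
#'                                         rest_s = 1))
#' rec
#' @export
make_synthetic_emg <- function(protocol,
                               profiles = default_motion_profiles(
                                 protocol$n_motions, protocol$n_channels)) {
  p <- protocol
  stopifnot(inherits(p, "protocol_spec"), length(profiles) == p$n_motions)
  for (pr in profiles) {
    stopifnot(inherits(pr, "motion_profile"),
              length(pr$gains) == p$n_channels)
    if (any(pr$band_centers + pr$bandwidths / 2 >= p$fs / 2))
      stop("profile band exceeds the Nyquist limit")
  }
  n_con <- round(p$contraction_s * p$fs)
  n_rest <- round(p$rest_s * p$fs)
  blocks_per_rep <- p$n_motions
  total <- p$n_reps * blocks_per_rep * (n_con + n_rest)

  with_seed(p$seed, {
    samples <- matrix(stats::rnorm(p$n_channels * total,
                                   sd = max(p$noise_sigma, 1e-12)),
                      nrow = p$n_channels)
    labels <- integer(total)
    env <- trapezoid_envelope(n_con, p$envelope_ramp)
    pos <- 0L
    for (rep_i in seq_len(p$n_reps)) {
      for (m in seq_len(p$n_motions)) {
        pr <- profiles[[m]]
        idx <- (pos + 1L):(pos + n_con)
        for (ch in seq_len(p$n_channels)) {
          carrier <- bandlimited_noise(n_con, p$fs, pr$band_centers[ch],
                                       pr$bandwidths[ch])
          samples[ch, idx] <- samples[ch, idx] +
            pr$gains[ch] * env * carrier
        }
        labels[idx] <- pr$class_id
        pos <- pos + n_con + n_rest       # rest keeps the baseline noise
      }
    }
    emg_recording(samples, p$fs, labels = labels, subject_id = "synthetic")
  })
}
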
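#' Multi-channel surface-EMG recording
#'
#' Container for a multi-channel sEMG recording: a channels x T sample
#' matrix, the sampling rate, and (optionally) a per-sample integer motion
#' label where 0 conventionally marks rest.
#'
#' @param samples numeric matrix, channels x T, or a numeric vector for a
#'   single channel.
#' @param fs sampling rate in Hz.
#' @param channel_names optional character vector, one name per channel.
#' @param labels optional integer vector of length T giving the motion class
#'   of every sample (0 = rest).
#' @param subject_id optional subject identifier string.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_names = NULL, labels = NULL,
                          subject_id = "synthetic") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (channels x T)")
  if (ncol(samples) < 1L) stop("recording has no samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples))
    stop("one channel name per channel required")
  if (!is.null(labels)) {
    if (length(labels) != ncol(samples))
      stop("`labels` must have one entry per sample")
    labels <- as.integer(labels)
  }
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         labels = labels, subject_id = subject_id),
    class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channel(s) x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Read a recording from delimited text
#'
#' Reads a delimited numeric text file with one row per sample and one
#' column per channel; an optional final integer label column is attached as
#' per-sample motion labels.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param sep field separator (default comma).
#' @param label_col `TRUE` if the last column holds integer motion labels.
#' @param channel_names optional channel names.
#' @param subject_id subject identifier.
#' @return An [emg_recording()].
#' @export
read_recording <- function(path, fs, sep = ",", label_col = FALSE,
                           channel_names = NULL, subject_id = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- tryCatch(
    utils::read.table(path, sep = sep, header = FALSE,
                      colClasses = "numeric"),
    error = function(e) stop("failed to parse '", path, "': ",
                             conditionMessage(e)))
  if (nrow(dat) == 0L) stop("no samples in ", path)
  m <- as.matrix(dat)
  if (any(!is.finite(m))) stop("non-numeric or non-finite entries in ", path)
  labels <- NULL
  if (isTRUE(label_col)) {
    if (ncol(m) < 2L) stop("label column requested but file has < 2 columns")
    labels <- as.integer(m[, ncol(m)])
    m <- m[, -ncol(m), drop = FALSE]
  }
  if (ncol(m) < 1L) stop("fewer than 1 channel")
  dimnames(m) <- NULL
  emg_recording(t(m), fs, channel_names = channel_names, labels = labels,
                subject_id = subject_id)
}

#' Write a recording as delimited text
#'
#' Inverse of [read_recording()]: one row per sample, one column per channel,
#' labels (if present) as a final integer column.
#'
#' @param rec an [emg_recording()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "emg_recording"))
  m <- t(rec$samples)
  # full double precision so a read-back is bit-identical
  txt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  if (!is.null(rec$labels)) txt <- cbind(txt, as.character(rec$labels))
  utils::write.table(txt, path, sep = sep, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

# Apply a per-channel function over the sample matrix, keeping metadata.
map_channels <- function(rec, f) {
  out <- rec
  out$samples <- t(apply(rec$samples, 1L, f))
  if (ncol(rec$samples) == 1L) out$samples <- matrix(out$samples, ncol = 1L)
  out
}

#' Band-pass filter a recording
#'
#' Butterworth band-pass applied identically to every channel. The stated
#' `order` is the order of the analog prototype of the band-pass (a 4th-order
#' band-pass uses a 2nd-order low/high pair). By default the filter is run
#' forward and backward (zero phase), which squares the magnitude response;
#' set `zero_phase = FALSE` for a single causal pass as used in streaming.
#'
#' @param rec an [emg_recording()].
#' @param low,high band edges in Hz; defaults 10 and 450 Hz, the usual sEMG
#'   energy band.
#' @param order band-pass filter order (even), default 4.
#' @param zero_phase forward-backward application (default `TRUE`).
#' @return Filtered [emg_recording()].
#' @export
bandpass_filter <- function(rec, low = 10, high = 450, order = 4,
                            zero_phase = TRUE) {
  stopifnot(inherits(rec, "emg_recording"))
  nyq <- rec$fs / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= nyq)
    stop(sprintf("high cutoff %g Hz must be below the Nyquist limit %g Hz",
                 high, nyq))
  if (order %% 2 != 0) stop("band-pass `order` must be even")
  filt <- signal::butter(order / 2, c(low, high) / nyq, type = "pass")
  appl <- if (zero_phase) {
    function(x) signal::filtfilt(filt, x)
  } else {
    function(x) as.numeric(signal::filter(filt, x))
  }
  map_channels(rec, appl)
}

# Biquad notch coefficients from center frequency and quality factor
# (standard audio-cookbook design). Returns list(b, a).
design_notch <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + al, -2 * cos(w0), 1 - al)
  list(b = b / a[1], a = a / a[1])
}

#' Notch filter a recording
#'
#' Second-order IIR notch (biquad) at `f0`, typically the 50 Hz power-line
#' frequency, applied identically to every channel. The notch width is set
#' by the quality factor `Q = f0 / bandwidth`.
#'
#' @param rec an [emg_recording()].
#' @param f0 notch center frequency in Hz (default 50).
#' @param Q quality factor (default 30, a narrow notch ~1.7 Hz wide at 50 Hz).
#' @param zero_phase forward-backward application (default `TRUE`).
#' @return Filtered [emg_recording()].
#' @export
notch_filter <- function(rec, f0 = 50, Q = 30, zero_phase = TRUE) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!(f0 > 0 && f0 < rec$fs / 2))
    stop(sprintf("notch frequency %g Hz must lie below the Nyquist limit %g Hz",
                 f0, rec$fs / 2))
  co <- design_notch(f0, rec$fs, Q)
  filt <- signal::Arma(b = co$b, a = co$a)
  appl <- if (zero_phase) {
    function(x) signal::filtfilt(filt, x)
  } else {
    function(x) as.numeric(signal::filter(filt, x))
  }
  map_channels(rec, appl)
}

#' Overlapping-window segmentation
#'
#' Splits a signal into fixed-length windows with fractional overlap. The
#' window length is `round(window_ms * fs / 1000)` samples and the hop is
#' `round(window * (1 - overlap_frac))`; a trailing partial window is
#' discarded. Start indices are 0-based.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param window_ms window length in milliseconds (default 250).
#' @param overlap_frac fraction of the window shared with its predecessor,
#'   in `[0, 1)` (default 0.10).
#' @return A list of class `segment_set` with elements `segments` (matrix,
#'   one row per window), `window_samples`, `step_samples`, `start_indices`.
#' @export
segment_signal <- function(x, fs, window_ms = 250, overlap_frac = 0.10) {
  stopifnot(is.numeric(x), fs > 0, overlap_frac >= 0, overlap_frac < 1)
  w <- round(window_ms * fs / 1000)
  if (w < 1L) stop("window shorter than one sample")
  if (length(x) < w)
    stop(sprintf("signal (%d samples) shorter than one %d-sample window",
                 length(x), w))
  step <- round(w * (1 - overlap_frac))
  if (step < 1L) stop("overlap too large: step would be zero")
  n <- floor((length(x) - w) / step) + 1L
  starts <- (seq_len(n) - 1L) * step            # 0-based
  seg <- matrix(0, nrow = n, ncol = w)
  for (i in seq_len(n)) seg[i, ] <- x[(starts[i] + 1L):(starts[i] + w)]
  structure(list(segments = seg, window_samples = w, step_samples = step,
                 start_indices = starts),
            class = "segment_set")
}

#' Majority label per segment
#'
#' Assigns each window the label held by more than half of its samples;
#' windows straddling a class boundary with no majority get `NA` (callers
#' drop them).
#'
#' @param labels integer per-sample labels.
#' @param segs a `segment_set` from [segment_signal()].
#' @return Integer vector, one (possibly `NA`) label per segment.
#' @export
segment_labels <- function(labels, segs) {
  stopifnot(inherits(segs, "segment_set"))
  w <- segs$window_samples
  vapply(segs$start_indices, function(s) {
    lab <- labels[(s + 1L):(s + w)]
    tab <- table(lab)
    top <- tab[which.max(tab)]
    if (top > w / 2) as.integer(names(top)) else NA_integer_
  }, integer(1))
}
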
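#' Feature matrix for classification
#'
#' N segments x M features with per-row motion labels and structured column
#' names of the form `<channel>.<feature>`. For the singular-value sets the
#' feature part is the mode index (`vmf1`, `imf2`, ...), so M equals
#' channels x modes; for the time-domain sets it is the descriptor name.
#'
#' @param values numeric N x M matrix.
#' @param row_labels integer motion class per row (0 = rest).
#' @param col_names character vector of M column names.
#' @param feature_set_id one of `"TD8"`, `"EMD_SVD"`, `"VMD_SVD"`,
#'   `"TD8+EMD_SVD"`, `"TD8+VMD_SVD"`, `"LS4"`, `"LS9"`.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, row_labels, col_names, feature_set_id) {
  stopifnot(is.matrix(values), nrow(values) == length(row_labels),
            ncol(values) == length(col_names))
  if (any(!is.finite(values))) stop("non-finite feature values")
  colnames(values) <- col_names
  structure(list(values = values, row_labels = as.integer(row_labels),
                 col_names = col_names, feature_set_id = feature_set_id),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d segment(s) x %d feature(s), %d class(es)\n",
              x$feature_set_id, nrow(x$values), ncol(x$values),
              length(unique(x$row_labels))))
  invisible(x)
}

#' Write a feature matrix as CSV
#'
#' One row per segment, a header of column names, and a final `label`
#' column.
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values)
  df$label <- fm$row_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Singular values of a matrix
#'
#' The singular values of X, i.e. the square roots of the eigenvalues of
#' t(X) %*% X, sorted descending.
#'
#' @param X numeric matrix.
#' @return Non-negative numeric vector of length `min(dim(X))`.
#' @export
svd_singular_values <- function(X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (any(!is.finite(X))) stop("non-finite entries")
  svd(X, nu = 0, nv = 0)$d
}

#' Singular-value feature of one segment
#'
#' Reduces a windowed mode segment to a single scalar. In the default
#' `"vector"` mode the segment is treated as a 1 x L matrix, whose only
#' singular value is its Euclidean norm. The `"reshape"` alternative folds
#' the segment into an r x c matrix with `r = floor(sqrt(L))` (row-major,
#' truncating leftover samples) and returns the leading singular value.
#'
#' @param x numeric segment.
#' @param shape `"vector"` (default) or `"reshape"`.
#' @return A non-negative scalar.
#' @export
segment_svd_feature <- function(x, shape = c("vector", "reshape")) {
  shape <- match.arg(shape)
  if (length(x) == 0L) stop("empty segment")
  if (shape == "vector") return(sqrt(sum(x^2)))
  r <- floor(sqrt(length(x)))
  cmax <- floor(length(x) / r)
  m <- matrix(x[seq_len(r * cmax)], nrow = r, byrow = TRUE)
  svd_singular_values(m)[1]
}

#' Eight time-domain EMG descriptors
#'
#' Computes, in order: MAV (mean absolute value), ZC (zero-crossing count
#' with amplitude deadband `zc_threshold`), WL (waveform length), RMS, SE
#' (standard error of the mean, STD/sqrt(n)), STD, VAR (sample variance,
#' n-1 denominator), and SNR (MAV/STD; 0 by convention for a constant
#' segment).
#'
#' @param x numeric segment, length >= 2.
#' @param zc_threshold minimum jump `|x[i] - x[i+1]|` for a sign change to
#'   count as a zero crossing (default 0).
#' @return Named numeric vector of length 8.
#' @export
td_features <- function(x, zc_threshold = 0) {
  if (length(x) < 2L) stop("segment too short")
  d <- diff(x)
  mav <- mean(abs(x))
  zc <- sum(x[-length(x)] * x[-1] < 0 & abs(d) > zc_threshold)
  wl <- sum(abs(d))
  rms <- sqrt(mean(x^2))
  v <- stats::var(x)
  std <- sqrt(v)
  se <- std / sqrt(length(x))
  snr <- if (std == 0) 0 else mav / std
  c(MAV = mav, ZC = zc, WL = wl, RMS = rms, SE = se, STD = std,
    VAR = v, SNR = snr)
}

# unbiased L-scale (second L-moment) estimator
l_scale <- function(x) {
  n <- length(x)
  xs <- sort(x)
  b0 <- mean(xs)
  b1 <- sum((seq_len(n) - 1) * xs) / (n * (n - 1))
  2 * b1 - b0
}

#' LS4 / LS9 time-domain feature sets
#'
#' The two compact descriptor sets popularized by open-source EMG feature
#' libraries. `LS4` is (MFL, MSR, WAMP, LS): maximum fractal length
#' `log10(sqrt(sum(diff(x)^2)))`, mean square root `mean(sqrt(|x|))`,
#' Wilson amplitude (count of successive differences exceeding
#' `wamp_threshold`), and the L-scale (second L-moment). `LS9` is
#' (LS, MAV, ZC, SSC, WL, RMS, IAV, DASDV, VAR), adding slope sign changes,
#' integrated absolute value and the difference absolute standard deviation
#' value `sqrt(mean(diff(x)^2))`.
#'
#' @param x numeric segment, length >= 3.
#' @param set `"LS4"` or `"LS9"`.
#' @param wamp_threshold WAMP amplitude threshold (default 0.05 signal
#'   units).
#' @param zc_threshold deadband for ZC as in [td_features()].
#' @return Named numeric vector of length 4 or 9.
#' @export
ls_features <- function(x, set = c("LS4", "LS9"), wamp_threshold = 0.05,
                        zc_threshold = 0) {
  set <- match.arg(set)
  if (length(x) < 3L) stop("segment too short")
  d <- diff(x)
  if (set == "LS4") {
    return(c(MFL = log10(sqrt(sum(d^2))),
             MSR = mean(sqrt(abs(x))),
             WAMP = sum(abs(d) > wamp_threshold),
             LS = l_scale(x)))
  }
  ssc <- sum(d[-length(d)] * d[-1] < 0)
  c(LS = l_scale(x),
    MAV = mean(abs(x)),
    ZC = sum(x[-length(x)] * x[-1] < 0 & abs(d) > zc_threshold),
    SSC = ssc,
    WL = sum(abs(d)),
    RMS = sqrt(mean(x^2)),
    IAV = sum(abs(x)),
    DASDV = sqrt(mean(d^2)),
    VAR = stats::var(x))
}

# Segment every channel identically; returns list(segsets = per-channel
# segment_set, labels = per-segment labels or NULL, keep = rows kept).
segment_recording <- function(rec, window_ms, overlap_frac) {
  segsets <- lapply(seq_len(nrow(rec$samples)), function(ch)
    segment_signal(rec$samples[ch, ], rec$fs, window_ms, overlap_frac))
  labels <- NULL
  keep <- seq_len(nrow(segsets[[1]]$segments))
  if (!is.null(rec$labels)) {
    labels <- segment_labels(rec$labels, segsets[[1]])
    keep <- which(!is.na(labels))
    labels <- labels[keep]
  } else {
    labels <- rep(0L, length(keep))
  }
  list(segsets = segsets, labels = labels, keep = keep)
}

# Shared driver for the two decomposition-based singular-value sets.
extract_decomp_svd <- function(rec, n_modes, window_ms, overlap_frac,
                               decomposer, tag, set_id, svd_shape) {
  stopifnot(inherits(rec, "emg_recording"))
  n_ch <- nrow(rec$samples)
  sr <- segment_recording(rec, window_ms, overlap_frac)
  n_seg <- length(sr$keep)
  vals <- matrix(0, nrow = n_seg, ncol = n_ch * n_modes)
  cn <- character(n_ch * n_modes)
  col <- 0L
  for (ch in seq_len(n_ch)) {
    modes <- decomposer(rec$samples[ch, ])     # list of <= n_modes vectors
    ss <- sr$segsets[[ch]]
    for (m in seq_len(n_modes)) {
      col <- col + 1L
      cn[col] <- sprintf("%s.%s%d", rec$channel_names[ch], tag, m)
      if (m <= length(modes)) {
        mv <- modes[[m]]
        vals[, col] <- vapply(sr$keep, function(i) {
          s0 <- ss$start_indices[i]
          segment_svd_feature(mv[(s0 + 1L):(s0 + ss$window_samples)],
                              shape = svd_shape)
        }, numeric(1))
      }                                        # else zero-filled column
    }
  }
  feature_matrix(vals, sr$labels, cn, set_id)
}

#' VMD singular-value features
#'
#' The spectro-temporal feature set: each channel is decomposed into `K`
#' variational mode functions, every mode is cut into overlapping windows,
#' and each windowed mode segment is reduced to its singular value. The
#' result has one row per segment and `channels * K` columns
#' (channel-major, modes in ascending center-frequency order).
#'
#' @param rec an [emg_recording()].
#' @param K number of VMD modes per channel.
#' @param window_ms,overlap_frac segmentation parameters (defaults 250 ms,
#'   10%).
#' @param alpha,tau,tol,max_iter,init,dc VMD settings, see
#'   [vmd_decompose()].
#' @param svd_shape per-segment reduction, see [segment_svd_feature()].
#' @return A [feature_matrix()] with `feature_set_id = "VMD_SVD"`.
#' @export
extract_vmd_svd <- function(rec, K, window_ms = 250, overlap_frac = 0.10,
                            alpha = 2000, tau = 0, tol = 1e-7,
                            max_iter = 500, init = "uniform", dc = FALSE,
                            svd_shape = "vector") {
  decomp <- function(x) {
    fit <- vmd_decompose(x, K = K, alpha = alpha, tau = tau, tol = tol,
                         max_iter = max_iter, init = init, dc = dc)
    lapply(seq_len(K), function(i) fit$modes[i, ])
  }
  extract_decomp_svd(rec, K, window_ms, overlap_frac, decomp, "vmf",
                     "VMD_SVD", svd_shape)
}

#' EMD singular-value features
#'
#' Baseline analogue of [extract_vmd_svd()] with intrinsic mode functions:
#' each channel is sifted into at most `n_imfs` IMFs and each windowed IMF
#' segment is reduced to its singular value. Channels that yield fewer than
#' `n_imfs` IMFs have the missing mode columns zero-filled so the matrix
#' shape is stable across recordings.
#'
#' @param rec an [emg_recording()].
#' @param n_imfs fixed number of IMF columns per channel (default 8).
#' @param window_ms,overlap_frac segmentation parameters.
#' @param config an [emd_config()].
#' @param svd_shape per-segment reduction, see [segment_svd_feature()].
#' @return A [feature_matrix()] with `feature_set_id = "EMD_SVD"`.
#' @export
extract_emd_svd <- function(rec, n_imfs = 8, window_ms = 250,
                            overlap_frac = 0.10, config = emd_config(),
                            svd_shape = "vector") {
  cfg <- config
  cfg$max_imfs <- as.integer(n_imfs)
  decomp <- function(x) emd_decompose(x, cfg)$imfs
  extract_decomp_svd(rec, n_imfs, window_ms, overlap_frac, decomp, "imf",
                     "EMD_SVD", svd_shape)
}

#' Time-domain feature sets per segment
#'
#' Applies [td_features()] (set `"TD8"`) or [ls_features()] (`"LS4"`,
#' `"LS9"`) to every windowed segment of every channel. Columns are
#' channel-major: all descriptors of channel 1, then channel 2, ...
#'
#' @param rec an [emg_recording()].
#' @param set `"TD8"`, `"LS4"` or `"LS9"`.
#' @param window_ms,overlap_frac segmentation parameters.
#' @param wamp_threshold,zc_threshold descriptor thresholds.
#' @return A [feature_matrix()].
#' @export
extract_td <- function(rec, set = c("TD8", "LS4", "LS9"), window_ms = 250,
                       overlap_frac = 0.10, wamp_threshold = 0.05,
                       zc_threshold = 0) {
  set <- match.arg(set)
  stopifnot(inherits(rec, "emg_recording"))
  featf <- switch(set,
    TD8 = function(x) td_features(x, zc_threshold),
    LS4 = function(x) ls_features(x, "LS4", wamp_threshold, zc_threshold),
    LS9 = function(x) ls_features(x, "LS9", wamp_threshold, zc_threshold))
  sr <- segment_recording(rec, window_ms, overlap_frac)
  n_ch <- nrow(rec$samples)
  blocks <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    ss <- sr$segsets[[ch]]
    rows <- t(vapply(sr$keep, function(i) {
      s0 <- ss$start_indices[i]
      featf(rec$samples[ch, (s0 + 1L):(s0 + ss$window_samples)])
    }, featf(rec$samples[ch, 1:ss$window_samples])))
    colnames(rows) <- sprintf("%s.%s", rec$channel_names[ch],
                              colnames(rows))
    blocks[[ch]] <- rows
  }
  vals <- do.call(cbind, blocks)
  feature_matrix(vals, sr$labels, colnames(vals), set)
}

#' Concatenate feature matrices column-wise
#'
#' Combines feature sets computed on the same segmentation of the same
#' recording (identical row counts and labels), e.g. TD8 + VMD-SVD.
#'
#' @param ... two or more [feature_matrix()] objects (or a single list of
#'   them).
#' @return A combined [feature_matrix()]; `feature_set_id` joins the inputs
#'   with `+`.
#' @export
combine_features <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "feature_matrix"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "feature_matrix")))
  if (length(sets) == 1L) return(sets[[1]])
  n <- nrow(sets[[1]]$values)
  for (s in sets[-1]) {
    if (nrow(s$values) != n) stop("row count mismatch between feature sets")
    if (!identical(s$row_labels, sets[[1]]$row_labels))
      stop("row labels differ between feature sets")
  }
  vals <- do.call(cbind, lapply(sets, `[[`, "values"))
  feature_matrix(vals, sets[[1]]$row_labels, colnames(vals),
                 paste(vapply(sets, `[[`, character(1), "feature_set_id"),
                       collapse = "+"))
}
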
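# Locations of strict local maxima/minima. Plateaus count once, at their
# midpoint. Returns list(max = indices, min = indices).
find_extrema <- function(x) {
  d <- diff(x)
  s <- sign(d)
  # collapse zero runs onto the preceding slope so plateau edges count once
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(max = integer(0), min = integer(0)))
  maxi <- integer(0); mini <- integer(0)
  prev_i <- nz[1]
  for (i in nz[-1]) {
    if (s[i] != s[prev_i]) {
      # turning point between samples prev_i+1 .. i (flat tops -> midpoint)
      idx <- as.integer(floor((prev_i + 1 + i) / 2))
      if (s[prev_i] > 0) maxi <- c(maxi, idx) else mini <- c(mini, idx)
    }
    prev_i <- i
  }
  list(max = maxi, min = mini)
}

# Count zero crossings (strict sign change, zeros skipped).
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}

# Cubic-spline envelope through extrema, mirrored two extrema beyond each
# end to tame end swings. Returns the envelope evaluated at 1..length(x).
spline_envelope <- function(x, idx) {
  n <- length(x)
  ti <- idx; vi <- x[idx]
  k <- min(2L, length(idx) - 1L)
  if (k >= 1L) {
    lt <- 2 * ti[1] - ti[1 + seq_len(k)]
    lv <- vi[1 + seq_len(k)]
    rt <- 2 * ti[length(ti)] - ti[length(ti) - seq_len(k)]
    rv <- vi[length(vi) - seq_len(k)]
    ti <- c(rev(lt), ti, rt); vi <- c(rev(lv), vi, rv)
  }
  stats::spline(ti, vi, xout = seq_len(n), method = "fmm")$y
}

#' Mean of the upper and lower cubic-spline envelopes
#'
#' The local-mean line used by EMD sifting: cubic splines through the local
#' maxima and through the local minima are averaged pointwise. Signals with
#' fewer than two maxima or two minima cannot be enveloped and raise a
#' condition of class `emgvmd_cannot_sift` (the caller treats such a signal
#' as the residue).
#'
#' @param x numeric vector.
#' @return Numeric vector `(upper + lower) / 2`, same length as `x`.
#' @export
envelope_mean <- function(x) {
  ex <- find_extrema(x)
  if (length(ex$max) < 2L || length(ex$min) < 2L)
    stop(structure(
      class = c("emgvmd_cannot_sift", "error", "condition"),
      list(message = "cannot sift: fewer than 2 maxima or 2 minima",
           call = sys.call(-1))))
  (spline_envelope(x, ex$max) + spline_envelope(x, ex$min)) / 2
}

#' Configuration for EMD
#'
#' @param max_imfs cap on the number of IMFs extracted (default 10).
#' @param sift_sd_tol Cauchy-style per-sift stopping threshold
#'   `sum((p_prev - p)^2) / sum(p_prev^2) < sift_sd_tol` (default 0.2, the
#'   classic sifting convention).
#' @param max_sifts cap on sifting iterations per IMF (default 100).
#' @return A list of class `emd_config`.
#' @export
emd_config <- function(max_imfs = 10L, sift_sd_tol = 0.2, max_sifts = 100L) {
  stopifnot(max_imfs >= 1, sift_sd_tol > 0, max_sifts >= 1)
  structure(list(max_imfs = as.integer(max_imfs), sift_sd_tol = sift_sd_tol,
                 max_sifts = as.integer(max_sifts)),
            class = "emd_config")
}

#' Sift one intrinsic mode function
#'
#' Repeatedly subtracts the envelope mean, `p <- p - envelope_mean(p)`,
#' until the relative change between consecutive sifts falls below
#' `sift_sd_tol` or `max_sifts` is reached.
#'
#' @param x numeric vector (must be siftable).
#' @param config an [emd_config()].
#' @return List with `imf` (numeric vector) and `n_sifts`.
#' @export
sift_imf <- function(x, config = emd_config()) {
  imf_gap <- function(p) {
    ex <- find_extrema(p)
    abs(length(ex$max) + length(ex$min) - count_zero_crossings(p))
  }
  p <- x - envelope_mean(x)           # propagates cannot_sift for flat input
  n_sifts <- 1L
  while (n_sifts < config$max_sifts) {
    nline <- tryCatch(envelope_mean(p),
                      emgvmd_cannot_sift = function(e) NULL)
    if (is.null(nline)) break
    p_new <- p - nline
    sd <- sum((p - p_new)^2) / (sum(p^2) + .Machine$double.eps)
    p <- p_new
    n_sifts <- n_sifts + 1L
    # accept only once the relative change is small AND the candidate
    # satisfies the IMF extrema/zero-crossing property
    if (sd < config$sift_sd_tol && imf_gap(p) <= 1L) break
  }
  list(imf = p, n_sifts = n_sifts)
}

#' Empirical Mode Decomposition
#'
#' Extracts intrinsic mode functions (IMFs) from fastest to slowest by
#' iterative sifting: each accepted IMF is subtracted from the running
#' residue and sifting restarts on what remains, until the residue is
#' monotonic (or nearly so) or `max_imfs` is reached. By construction the
#' IMFs and residue sum back to the input exactly.
#'
#' @param x numeric vector, length >= 4.
#' @param config an [emd_config()].
#' @return An object of class `emd_result`: `imfs` (list of numeric
#'   vectors, possibly empty) and `residue`.
#' @examples
#' t <- seq(0, 1, length.out = 1000)
#' x <- cos(2 * pi * 50 * t) + cos(2 * pi * 5 * t)
#' fit <- emd_decompose(x)
#' length(fit$imfs)
#' @export
emd_decompose <- function(x, config = emd_config()) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("signal contains non-finite samples")
  if (length(x) < 4L) stop("signal too short for sifting")
  imfs <- list()
  resid <- x
  while (length(imfs) < config$max_imfs) {
    res <- tryCatch(sift_imf(resid, config),
                    emgvmd_cannot_sift = function(e) NULL)
    if (is.null(res)) break
    imfs[[length(imfs) + 1L]] <- res$imf
    resid <- resid - res$imf
  }
  structure(list(imfs = imfs, residue = resid), class = "emd_result")
}

#' @export
print.emd_result <- function(x, ...) {
  cat(sprintf("<emd_result> %d IMF(s), T=%d\n",
              length(x$imfs), length(x$residue)))
  invisible(x)
}
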
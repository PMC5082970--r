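#' Discard initial volumes of a run
#'
#' Drops the first `n` frames (T1-equilibration frames); the remaining frames
#' are preserved bit-exactly.
#'
#' @param run A [bold_run()].
#' @param n Number of frames to drop (default 4).
#' @return A [bold_run()] with `T - n` frames.
#' @export
discard_initial_volumes <- function(run, n = 4L) {
  stopifnot(inherits(run, "bold_run"))
  T <- n_frames(run)
  n <- as.integer(n)
  if (n < 0) stop_named("discard_initial_volumes: n must be >= 0")
  if (n >= T)
    stop_named("discard_initial_volumes: n = %d >= T = %d leaves no frames",
               n, T)
  if (n == 0L) return(run)
  out <- run
  out$data <- run$data[, , , (n + 1):T, drop = FALSE]
  out
}

# Order-4 Butterworth band-pass coefficients for sampling interval tr_s.
butter_coefs <- function(band_hz, tr_s) {
  nyq <- 1 / (2 * tr_s)
  if (!(band_hz[1] > 0 && band_hz[1] < band_hz[2] && band_hz[2] < nyq))
    stop_named("bandpass: band (%g, %g) Hz invalid for TR = %g s (Nyquist %g Hz)",
               band_hz[1], band_hz[2], tr_s, nyq)
  signal::butter(4, band_hz / nyq, type = "pass")
}

# Zero-phase forward-backward IIR filtering with odd-reflection padding to
# suppress edge transients (the filtfilt in `signal` does not pad).
filtfilt_padded <- function(x, flt) {
  b <- flt$b; a <- flt$a
  padlen <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= padlen + 1L)
    stop_named("bandpass: series of length %d too short; need more than %d samples",
               n, padlen + 1L)
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- c(pre, x, post)
  y <- as.numeric(signal::filter(b, a, y))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(padlen + 1):(padlen + n)]
}

# FFT band-pass of the columns of a T x V matrix (hard frequency mask;
# exactly zero phase and exactly zero outside the band).
fft_bandpass <- function(M, tr_s, band_hz) {
  T <- nrow(M)
  f <- (seq_len(T) - 1) / (T * tr_s)
  f <- pmin(f, 1 / tr_s - f)
  keep <- f >= band_hz[1] & f <= band_hz[2]
  F <- stats::mvfft(M)
  F[!keep, ] <- 0
  Re(stats::mvfft(F, inverse = TRUE)) / T
}

#' Band-pass filter a run or a time series
#'
#' Phase-insensitive (zero phase lag) band-pass filtering. Two equivalent
#' implementations are available: `"butter"`, an order-4 Butterworth applied
#' forward and backward with odd-reflection padding, and `"fft"`, a hard
#' frequency mask. Both attenuate by well over 20 dB one octave outside the
#' band and introduce no lag. For a single numeric series the default is the
#' Butterworth filter; for a 4-D run the default is the FFT filter, which is
#' applied to all voxels at once. The per-voxel temporal mean is removed.
#'
#' @param x A [bold_run()] or a numeric vector.
#' @param band_hz Pass band `(low, high)` in Hz (default 0.01-0.08).
#' @param tr_s Sampling interval; taken from the run when `x` is a run.
#' @param method `"fft"` or `"butter"`; see above for defaults.
#' @return Object of the same type as `x`, filtered and demeaned.
#' @export
bandpass <- function(x, band_hz = c(0.01, 0.08), tr_s = NULL, method = NULL) {
  if (inherits(x, "bold_run")) {
    method <- method %||% "fft"
    tr_s <- x$tr_s
    butter_coefs(band_hz, tr_s)  # validates the band for this TR
    d <- dim(x$data)
    M <- t(matrix(x$data, prod(d[1:3]), d[4]))   # T x V
    M <- sweep(M, 2, colMeans(M))
    M <- if (method == "fft") fft_bandpass(M, tr_s, band_hz)
         else {
           flt <- butter_coefs(band_hz, tr_s)
           apply(M, 2, filtfilt_padded, flt = flt)
         }
    M <- sweep(M, 2, colMeans(M))
    out <- x
    out$data <- array(t(M), d)
    out
  } else {
    stopifnot(is.numeric(x), !is.null(tr_s))
    method <- method %||% "butter"
    x0 <- x - mean(x)
    y <- if (method == "fft") drop(fft_bandpass(cbind(x0), tr_s, band_hz))
         else filtfilt_padded(x0, butter_coefs(band_hz, tr_s))
    y - mean(y)
  }
}

# Dense one-axis Gaussian smoothing operator with whole-sample reflection at
# the boundaries; rows sum to 1 so constant images are preserved exactly.
gauss_operator <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  off <- (-r):r
  w <- exp(-off^2 / (2 * sigma^2))
  w <- w / sum(w)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + off
    j <- ifelse(j < 1, 2 - j, j)
    j <- ifelse(j > n, 2 * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    for (k in seq_along(j)) S[i, j[k]] <- S[i, j[k]] + w[k]
  }
  S
}

#' Spatially smooth a run
#'
#' Frame-wise separable 3-D Gaussian smoothing with
#' `sigma = fwhm / (2 sqrt(2 ln 2))` per axis, converted from mm to voxels via
#' the grid voxel size. Boundaries use whole-sample reflection, so the frame
#' mean over the mask is preserved (exactly, for an all-true mask).
#'
#' @param run A [bold_run()].
#' @param fwhm_mm Full width at half maximum in mm; 0 is the identity.
#' @return The smoothed [bold_run()].
#' @export
smooth_run <- function(run, fwhm_mm = 8) {
  stopifnot(inherits(run, "bold_run"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(run)
  d <- dim(run$data)
  sig <- fwhm_mm / (2 * sqrt(2 * log(2))) / run$grid$voxel_size_mm
  A <- run$data
  # axis 1
  S <- gauss_operator(d[1], sig[1])
  A <- array(S %*% matrix(A, d[1]), d)
  # axis 2
  S <- gauss_operator(d[2], sig[2])
  A <- aperm(A, c(2, 1, 3, 4))
  A <- aperm(array(S %*% matrix(A, d[2]), d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  # axis 3
  S <- gauss_operator(d[3], sig[3])
  A <- aperm(A, c(3, 1, 2, 4))
  A <- aperm(array(S %*% matrix(A, d[3]), d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  out <- run
  out$data <- A
  out
}

#' Preprocess a run (discard, band-pass, smooth)
#'
#' Applies the post-registration preprocessing chain in the standard order:
#' initial-volume discard, temporal band-pass, spatial smoothing. Head-motion
#' realignment and slice-timing correction are upstream, registration-level
#' steps that the synthetic data do not need; requesting them logs a warning
#' and does nothing.
#'
#' @param run A [bold_run()].
#' @param n_discard Frames to drop (default 4).
#' @param band_hz Pass band in Hz (default 0.01-0.08).
#' @param smooth_fwhm_mm Smoothing FWHM in mm (default 8).
#' @param bandpass_method `"fft"` (default for runs) or `"butter"`.
#' @param realign,slice_timing If `TRUE`, warn that these are out of scope.
#' @return The preprocessed [bold_run()].
#' @export
preprocess_run <- function(run, n_discard = 4L, band_hz = c(0.01, 0.08),
                           smooth_fwhm_mm = 8, bandpass_method = "fft",
                           realign = FALSE, slice_timing = FALSE) {
  if (isTRUE(realign))
    warning("realignment requested but not implemented (no-op): input is assumed registered")
  if (isTRUE(slice_timing))
    warning("slice-timing correction requested but not implemented (no-op)")
  run <- discard_initial_volumes(run, n_discard)
  run <- bandpass(run, band_hz, method = bandpass_method)
  smooth_run(run, smooth_fwhm_mm)
}
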
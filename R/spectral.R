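#' Burg autoregressive power spectral density
#'
#' Fits an AR model by the Burg reflection-coefficient recursion
#' (via [stats::ar.burg()], mean removed first) and evaluates the AR transfer
#' function on a uniform frequency grid from 0 to Nyquist. Order 6 is the
#' conventional choice for 1-minute RR segments resampled at 2 Hz, where the
#' segment is too short for a stable periodogram.
#'
#' The one-sided density is `S(f) = 2 s2 / fs / |1 - sum_k a_k e^{-2 pi i f
#' k / fs}|^2` with `s2` the innovation variance; absolute normalization is
#' conventional and cancels in band-power ratios such as LF/HF.
#'
#' @param x numeric segment (e.g. the 120 samples of an `"rr_segment"`) or an
#'   `"rr_segment"` itself.
#' @param fs sampling rate in Hz (default 2, the pipeline's resampling rate).
#' @param order AR order (default 6).
#' @param n_freq number of grid points over `[0, fs/2]` (default 1024, at
#'   least 512 recommended for stable band integrals).
#' @return a `"spectral_estimate"`: list with `freq` (Hz) and nonnegative
#'   `psd`.
#' @export
burg_psd <- function(x, fs = 2, order = 6, n_freq = 1024) {
  if (inherits(x, "rr_segment")) x <- x$samples
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("segment contains non-finite values")
  if (length(x) <= order) stop("segment shorter than AR order")
  if (pop_sd(x) == 0) stop("degenerate input: zero-variance segment")
  if (n_freq < 2) stop("`n_freq` must be >= 2")
  fit <- stats::ar.burg(x, aic = FALSE, order.max = order, demean = TRUE)
  a <- fit$ar
  s2 <- fit$var.pred
  f <- seq(0, fs / 2, length.out = n_freq)
  den <- abs(1 - exp(-2i * pi * outer(f / fs, seq_along(a))) %*% a)^2
  structure(list(freq = f, psd = as.numeric(2 * s2 / fs / den)),
            class = "spectral_estimate")
}

#' Band power by trapezoidal integration
#'
#' Integrates the PSD over `[f_lo, f_hi]`, interpolating the density linearly
#' at the band edges so the integral is exact for a piecewise-linear PSD.
#'
#' @param est a `"spectral_estimate"` from [burg_psd()].
#' @param f_lo,f_hi band edges in Hz, `0 <= f_lo < f_hi <= Nyquist`.
#' @return the integrated power (nonnegative scalar).
#' @export
band_power <- function(est, f_lo, f_hi) {
  stopifnot(inherits(est, "spectral_estimate"))
  if (!(f_lo >= min(est$freq) && f_hi <= max(est$freq))) {
    stop("band outside the frequency grid")
  }
  if (!(f_lo < f_hi)) stop("band must have positive width (f_lo < f_hi)")
  inner <- est$freq > f_lo & est$freq < f_hi
  fx <- c(f_lo, est$freq[inner], f_hi)
  fy <- c(stats::approx(est$freq, est$psd, xout = f_lo)$y,
          est$psd[inner],
          stats::approx(est$freq, est$psd, xout = f_hi)$y)
  sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
}

#' Frequency-domain HRV indices of one segment
#'
#' LF is the power in 0.04-0.15 Hz, HF in 0.15-0.4 Hz (short-term HRV
#' convention), from the Burg AR spectrum; LF/HF is their ratio, a
#' sympathovagal-balance proxy.
#'
#' @inheritParams burg_psd
#' @return a `"frequency_indices"` list: `lf`, `hf`, `lf_hf` (`NA` when
#'   `hf == 0`).
#' @export
frequency_indices <- function(x, fs = 2, order = 6, n_freq = 1024) {
  est <- burg_psd(x, fs = fs, order = order, n_freq = n_freq)
  lf <- band_power(est, 0.04, 0.15)
  hf <- band_power(est, 0.15, 0.40)
  structure(list(lf = lf, hf = hf,
                 lf_hf = if (hf > 0) lf / hf else NA_real_),
            class = "frequency_indices")
}
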
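#' Detect R peaks in a single-lead ECG (Pan-Tompkins)
#'
#' Standard Pan-Tompkins stages: band-pass 5-15 Hz (zero-phase Butterworth),
#' five-point derivative, squaring, 150 ms moving-window integration, then
#' adaptive dual thresholds on the integrated signal with search-back for
#' missed beats. A 200 ms refractory period is enforced and each accepted
#' detection is refined to the local maximum of the band-passed signal.
#'
#' @param x numeric ECG waveform (single channel) or an `"ecg_record"` from
#'   [synth_ecg()] / [read_wfdb()].
#' @param fs sampling rate in Hz (ignored when `x` is an `"ecg_record"`);
#'   must be at least 100 Hz.
#' @return integer vector of R-peak sample indices (1-based), strictly
#'   increasing.
#' @export
detect_r_peaks <- function(x, fs = NULL) {
  if (inherits(x, "ecg_record")) {
    fs <- x$fs
    x <- x$samples
  }
  if (is.null(fs) || fs < 100) stop("sampling rate must be >= 100 Hz")
  x <- as.numeric(x)
  n <- length(x)
  if (n / fs < 10) stop("record too short: need at least 10 s of signal")
  if (pop_sd(x) == 0) stop("flat signal: no QRS complexes detectable")

  bp <- signal::butter(3, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x - mean(x))

  # five-point derivative (Pan-Tompkins kernel), squared
  dk <- c(1, 2, 0, -2, -1) * fs / 8
  dx <- stats::filter(xf, dk, sides = 2)
  dx[is.na(dx)] <- 0
  sq <- as.numeric(dx)^2

  w <- max(1L, round(0.150 * fs))
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 1)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  # candidate fiducial marks: local maxima of the integrated signal,
  # separated by the 200 ms refractory period
  refr <- round(0.200 * fs)
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 0]
  if (length(cand) == 0) stop("no candidate peaks found (flat or degenerate signal)")

  init <- mwi[seq_len(min(n, 2 * fs))]
  spki <- max(init) * 0.6
  npki <- mean(init) * 0.5
  thr1 <- npki + 0.25 * (spki - npki)

  qrs <- integer(0)
  rr_hist <- numeric(0)
  last_cand_below <- integer(0)
  for (p in cand) {
    if (length(qrs) && (p - qrs[length(qrs)]) < refr) next
    if (mwi[p] >= thr1) {
      qrs <- c(qrs, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      if (length(qrs) >= 2) {
        rr_hist <- c(rr_hist, diff(utils::tail(qrs, 2)))
        if (length(rr_hist) > 8) rr_hist <- utils::tail(rr_hist, 8)
      }
      last_cand_below <- integer(0)
    } else {
      npki <- 0.125 * mwi[p] + 0.875 * npki
      last_cand_below <- c(last_cand_below, p)
      # search-back: if the expected beat is overdue, take the best missed
      # candidate above the lower threshold
      if (length(qrs) && length(rr_hist)) {
        if ((p - qrs[length(qrs)]) > 1.66 * mean(rr_hist)) {
          ok <- last_cand_below[mwi[last_cand_below] >= 0.5 * thr1 &
                                  last_cand_below - qrs[length(qrs)] >= refr]
          if (length(ok)) {
            back <- ok[which.max(mwi[ok])]
            qrs <- sort(c(qrs, back))
            spki <- 0.25 * mwi[back] + 0.75 * spki
            last_cand_below <- integer(0)
          }
        }
      }
    }
    thr1 <- npki + 0.25 * (spki - npki)
  }
  if (length(qrs) < 2) stop("QRS detection failed: fewer than 2 beats found")

  # refine each fiducial mark to the R peak in the raw (mean-removed) signal;
  # the integrator (sides = 1) delays the peak by up to one window, and the
  # raw waveform keeps the R apex undistorted by the band-pass
  xr <- x - mean(x)
  peaks <- vapply(qrs, function(p) {
    lo <- max(1L, as.integer(p) - as.integer(w))
    hi <- min(n, as.integer(p) + 2L)
    lo + which.max(xr[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # re-impose the refractory period after refinement
  keep <- rep(TRUE, length(peaks))
  last <- peaks[1]
  for (i in seq_along(peaks)[-1]) {
    if (peaks[i] - last < refr) keep[i] <- FALSE else last <- peaks[i]
  }
  peaks[keep]
}

#' RR-interval series from beat indices
#'
#' @param indices strictly increasing beat sample indices.
#' @param fs sampling rate in Hz.
#' @return an `"rr_series"`: list with `beat_times` (s from record start),
#'   `intervals` (s, one per successive beat pair) and a logical
#'   `corrected` flag per interval (all `FALSE` here; set by
#'   [correct_rr_local_median()]).
#' @export
rr_from_peaks <- function(indices, fs) {
  if (length(indices) < 2) stop("need at least 2 beat indices")
  if (any(diff(indices) <= 0)) stop("beat indices must be strictly increasing")
  stopifnot(fs > 0)
  beat_times <- as.numeric(indices) / fs
  new_rr_series(beat_times)
}

new_rr_series <- function(beat_times, corrected = NULL) {
  intervals <- diff(beat_times)
  if (any(intervals <= 0)) stop("beat times must be strictly increasing")
  if (is.null(corrected)) corrected <- rep(FALSE, length(intervals))
  structure(list(beat_times = beat_times, intervals = intervals,
                 corrected = corrected),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("RR series: %d beats over %.1f s, mean RR %.3f s, %d corrected\n",
              length(x$beat_times), diff(range(x$beat_times)),
              mean(x$intervals), sum(x$corrected)))
  invisible(x)
}

#' Local-median artifact correction of RR intervals
#'
#' Each interval deviating from the median of its surrounding window by more
#' than `tolerance * median` is replaced by that local median and flagged.
#' Beat times are rebuilt by cumulative summation from the first beat, so the
#' corrected series is self-consistent.
#'
#' @param rr an `"rr_series"`.
#' @param window odd window width in beats (default 5).
#' @param tolerance fractional deviation triggering replacement (default 0.2).
#' @return a corrected `"rr_series"` with updated `corrected` flags.
#' @export
correct_rr_local_median <- function(rr, window = 5, tolerance = 0.2) {
  stopifnot(inherits(rr, "rr_series"))
  if (window < 3 || window %% 2 == 0) stop("`window` must be odd and >= 3")
  iv <- rr$intervals
  if (length(iv) < window) return(rr)  # too short to judge: no-op
  med <- stats::runmed(iv, window, endrule = "median")
  bad <- abs(iv - med) > tolerance * med
  iv[bad] <- med[bad]
  beat_times <- c(rr$beat_times[1], rr$beat_times[1] + cumsum(iv))
  new_rr_series(beat_times, corrected = rr$corrected | bad)
}

#' Split an RR series into nonoverlapping 1-minute tachogram slices
#'
#' Minute `k` (0-based) owns the tachogram points — interval values stamped at
#' the time of their closing beat — with time in the half-open window
#' `[60k, 60(k+1))` seconds. Slices with fewer than `min_beats` points are
#' marked invalid (a likely detector failure; normal sinus rhythm yields
#' 60-100 beats per minute).
#'
#' @param rr an `"rr_series"`.
#' @param hours analysis span from record start (default 6, i.e. up to 360
#'   minutes); shorter records yield fewer slices with a warning.
#' @param min_beats minimum tachogram points for a valid minute (default 30).
#' @return list of `"rr_minute"` slices: `minute`, `times`, `intervals`,
#'   `n_beats`, `valid`.
#' @export
segment_minutes <- function(rr, hours = 6, min_beats = 30) {
  stopifnot(inherits(rr, "rr_series"), hours > 0)
  times <- rr$beat_times[-1]
  vals <- rr$intervals
  requested <- as.integer(round(hours * 60))
  available <- as.integer(floor(max(times) / 60)) + 1L
  n_min <- min(requested, available)
  if (available < requested) {
    warning(sprintf("record covers only %d of %d requested minutes",
                    available, requested))
  }
  minute_of <- floor(times / 60)
  lapply(seq_len(n_min) - 1L, function(k) {
    sel <- minute_of == k
    structure(list(minute = k, times = times[sel], intervals = vals[sel],
                   n_beats = sum(sel), valid = sum(sel) >= min_beats),
              class = "rr_minute")
  })
}

#' Resample a 1-minute tachogram slice to a uniform 2 Hz grid
#'
#' Interpolates the tachogram (interval value versus closing-beat time) with a
#' natural cubic spline and evaluates it on the 0.5 s grid covering the
#' minute, yielding exactly 120 samples. Outside the span of the observed
#' beats the edge values are held constant (clamped).
#'
#' @param slice an `"rr_minute"` from [segment_minutes()].
#' @param method `"spline"` (default, natural cubic) or `"linear"`.
#' @return an `"rr_segment"`: `minute`, `samples` (length 120), `n_beats`,
#'   `valid`. Invalid slices propagate as invalid segments with `NA` samples.
#' @export
resample_2hz <- function(slice, method = c("spline", "linear")) {
  stopifnot(inherits(slice, "rr_minute"))
  method <- match.arg(method)
  grid <- 60 * slice$minute + seq(0, 59.5, by = 0.5)
  if (!slice$valid) {
    return(structure(list(minute = slice$minute,
                          samples = rep(NA_real_, 120L),
                          n_beats = slice$n_beats, valid = FALSE),
                     class = "rr_segment"))
  }
  tt <- pmin(pmax(grid, min(slice$times)), max(slice$times))
  samples <- if (method == "spline") {
    stats::splinefun(slice$times, slice$intervals, method = "natural")(tt)
  } else {
    stats::approx(slice$times, slice$intervals, xout = tt, rule = 2)$y
  }
  structure(list(minute = slice$minute, samples = samples,
                 n_beats = slice$n_beats, valid = TRUE),
            class = "rr_segment")
}

#' Per-minute HRV features of an RR series
#'
#' Runs the full short-term pipeline on one recording: 1-minute segmentation,
#' 2 Hz spline resampling, then per valid minute classical sample entropy,
#' nonparametric sample entropy, and Burg AR(6) band powers (LF, HF, LF/HF).
#' By default both entropies are computed on the 120-sample resampled series
#' (the same input the spectral stage uses); `entropy_on = "raw"` computes
#' them on the raw per-minute intervals instead.
#'
#' @param rr an `"rr_series"`.
#' @param hours analysis span (default 6).
#' @param m embedding dimension for both entropies.
#' @param r SampEn tolerance (multiple of segment SD).
#' @param entropy_on `"resampled"` (default) or `"raw"`.
#' @param min_beats minimum beats per valid minute.
#' @param interp_method interpolation for [resample_2hz()].
#' @param ar_order,n_freq Burg spectrum settings (see [burg_psd()]).
#' @return data frame with one row per minute: `minute`, `valid`, `n_beats`,
#'   `sampen`, `npsampen`, `lf`, `hf`, `lf_hf`.
#' @export
rr_features <- function(rr, hours = 6, m = 2, r = 0.2,
                        entropy_on = c("resampled", "raw"),
                        min_beats = 30, interp_method = "spline",
                        ar_order = 6, n_freq = 1024) {
  entropy_on <- match.arg(entropy_on)
  slices <- segment_minutes(rr, hours = hours, min_beats = min_beats)
  rows <- lapply(slices, function(sl) {
    base <- data.frame(minute = sl$minute, valid = sl$valid,
                       n_beats = sl$n_beats, sampen = NA_real_,
                       npsampen = NA_real_, lf = NA_real_, hf = NA_real_,
                       lf_hf = NA_real_)
    if (!sl$valid) return(base)
    seg <- resample_2hz(sl, method = interp_method)
    ex <- if (entropy_on == "resampled") seg$samples else sl$intervals
    if (length(ex) >= m + 2 && pop_sd(ex) > 0) {
      d <- template_distances(ex, m)
      base$sampen <- sampen(ex, m = m, r = r, distances = d)$value
      base$npsampen <- npsampen(ex, m = m, distances = d)$value
    }
    if (pop_sd(seg$samples) > 0) {
      fi <- frequency_indices(seg$samples, order = ar_order, n_freq = n_freq)
      base$lf <- fi$lf
      base$hf <- fi$hf
      base$lf_hf <- fi$lf_hf
    }
    base
  })
  do.call(rbind, rows)
}

#' Per-minute HRV features straight from an ECG record
#'
#' Convenience wrapper: [detect_r_peaks()], [rr_from_peaks()],
#' [correct_rr_local_median()], then [rr_features()].
#'
#' @param ecg an `"ecg_record"` (or numeric waveform with `fs` given).
#' @param fs sampling rate when `ecg` is a bare numeric vector.
#' @param ... passed to [rr_features()].
#' @return see [rr_features()].
#' @export
ecg_features <- function(ecg, fs = NULL, ...) {
  peaks <- detect_r_peaks(ecg, fs)
  fs_use <- if (inherits(ecg, "ecg_record")) ecg$fs else fs
  rr <- correct_rr_local_median(rr_from_peaks(peaks, fs_use))
  rr_features(rr, ...)
}
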
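#' Specification of a synthetic RR cohort
#'
#' Describes a cohort of overnight RR recordings with three severity groups.
#' The RR dynamics model is a sum of sinusoids plus white noise: all groups
#' share a respiratory-band oscillation (high-frequency, vagally mediated)
#' and a low-frequency component; the OSA groups additionally carry a slow
#' cyclic bradycardia-tachycardia oscillation (the hallmark of recurrent
#' apneas, period tens of seconds) active during a fraction of the night
#' (`prevalence`), with reduced respiratory amplitude and reduced broadband
#' noise — i.e. more regular, lower-entropy, more sympathetically dominated
#' dynamics as severity increases. This is a test fixture emulating the
#' contrast of interest, not a physiological model.
#'
#' Group defaults (amplitudes in seconds of RR modulation):
#' normal — respiratory 0.040 at 0.25 Hz, LF 0.010 at 0.095 Hz, noise SD
#' 0.030, no apnea cycle, AHI in (0, 5); mild-moderate — respiratory 0.025,
#' LF 0.020, noise SD 0.014, cycle 0.070 with 50 s period at prevalence 0.7,
#' AHI in (5, 30); severe — respiratory 0.015, LF 0.030, noise SD 0.012,
#' cycle 0.080 with 45 s period at prevalence 0.85, AHI in (30, 80).
#' Per-recording individual differences are modelled as independent lognormal
#' jitters (`jitter_sd` on the log scale) on the structured amplitudes and on
#' the noise SD.
#'
#' @param n_normal,n_mosa,n_sosa group sizes (default 20/14/26).
#' @param duration_h recording duration in hours (default 6).
#' @param mean_rr mean RR interval in seconds (default 1.0).
#' @param jitter_sd log-scale SD of per-recording amplitude jitter
#'   (default 0.15).
#' @param seed integer seed for the whole cohort.
#' @return a `"cohort_spec"` list, including a `groups` list of per-group
#'   parameter sets.
#' @export
cohort_spec <- function(n_normal = 20, n_mosa = 14, n_sosa = 26,
                        duration_h = 6, mean_rr = 1.0, jitter_sd = 0.15,
                        seed = 1) {
  stopifnot(n_normal >= 0, n_mosa >= 0, n_sosa >= 0, duration_h > 0,
            mean_rr > 0.3)
  groups <- list(
    N = list(resp_amp = 0.040, resp_freq = 0.25, lf_amp = 0.010,
             lf_freq = 0.095, noise_sd = 0.030, cycle_amp = 0,
             cycle_period = 50, prevalence = 0, ahi_range = c(0, 5)),
    MOSA = list(resp_amp = 0.025, resp_freq = 0.25, lf_amp = 0.020,
                lf_freq = 0.095, noise_sd = 0.014, cycle_amp = 0.070,
                cycle_period = 50, prevalence = 0.7, ahi_range = c(5, 30)),
    SOSA = list(resp_amp = 0.015, resp_freq = 0.25, lf_amp = 0.030,
                lf_freq = 0.095, noise_sd = 0.012, cycle_amp = 0.080,
                cycle_period = 45, prevalence = 0.85, ahi_range = c(30, 80)))
  structure(list(n = c(N = n_normal, MOSA = n_mosa, SOSA = n_sosa),
                 duration_h = duration_h, mean_rr = mean_rr,
                 jitter_sd = jitter_sd, seed = seed, groups = groups),
            class = "cohort_spec")
}

#' Synthesize one overnight RR series with OSA-like regularity structure
#'
#' Beat intervals are built on a provisional uniform beat grid (spacing
#' `mean_rr`): each interval is the mean RR plus the sinusoidal modulations of
#' its group evaluated at the provisional beat time, plus white noise; beat
#' times are then the cumulative sums. The apnea cycle is switched on per
#' cycle-length block with probability `prevalence`, emulating episodic runs
#' of apneas. Intervals are clamped at 0.3 s.
#'
#' @param group `"N"`, `"MOSA"` or `"SOSA"`.
#' @param spec a [cohort_spec()] (its per-group parameters are used).
#' @param duration_h recording length in hours; default from `spec`.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @param jitter multiplicative per-recording jitter applied to the
#'   structured (sinusoidal) amplitudes (default 1 = none;
#'   [generate_cohort()] draws it).
#' @param noise_jitter multiplicative per-recording jitter on the noise SD,
#'   drawn independently of `jitter` so the noise-to-structure ratio — what
#'   the entropy estimators respond to, both being affine invariant —
#'   genuinely varies between recordings.
#' @return list with `rr` (an `"rr_series"`) and `ahi` (drawn uniformly in
#'   the group's AHI band).
#' @export
synth_rr <- function(group, spec = cohort_spec(), duration_h = NULL,
                     seed = NULL, jitter = 1, noise_jitter = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  g <- spec$groups[[match.arg(group, names(spec$groups))]]
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration_h)) duration_h <- spec$duration_h
  dur <- duration_h * 3600
  n_beats <- ceiling(dur / spec$mean_rr) + 10L
  t0 <- (seq_len(n_beats) - 1L) * spec$mean_rr
  phi <- stats::runif(3, 0, 2 * pi)
  cyc_on <- if (g$prevalence > 0) {
    blocks <- floor(t0 / g$cycle_period)
    active <- stats::rbinom(max(blocks) + 1L, 1L, g$prevalence)
    active[blocks + 1L] == 1L
  } else rep(FALSE, n_beats)
  iv <- spec$mean_rr +
    jitter * g$resp_amp * sin(2 * pi * g$resp_freq * t0 + phi[1]) +
    jitter * g$lf_amp * sin(2 * pi * g$lf_freq * t0 + phi[2]) +
    jitter * g$cycle_amp * cyc_on * sin(2 * pi * t0 / g$cycle_period + phi[3]) +
    stats::rnorm(n_beats, 0, noise_jitter * g$noise_sd)
  iv <- pmax(iv, 0.3)
  beat_times <- cumsum(c(0, iv))
  beat_times <- beat_times[beat_times <= dur + spec$mean_rr]
  ahi <- stats::runif(1, g$ahi_range[1], g$ahi_range[2])
  list(rr = new_rr_series(beat_times), ahi = ahi, group = group)
}

#' Generate a full synthetic cohort
#'
#' Draws every recording from a single RNG stream seeded by `spec$seed`, so
#' the whole cohort is reproducible bit-for-bit from the spec alone.
#'
#' @param spec a [cohort_spec()].
#' @return list of records, each a list with `id`, `group`, `ahi`, `rr`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  records <- list()
  for (grp in names(spec$n)) {
    for (i in seq_len(spec$n[[grp]])) {
      jit <- exp(stats::rnorm(2, 0, spec$jitter_sd))
      rec <- synth_rr(grp, spec, jitter = jit[1], noise_jitter = jit[2])
      rec$id <- sprintf("%s%02d", tolower(grp), i)
      records[[length(records) + 1L]] <- rec
    }
  }
  records
}

#' Write a cohort as RR CSV files plus an AHI label file
#'
#' One `rr_<id>.csv` per recording (columns `time_s,interval_s,flag`) and an
#' `ahi.csv` (columns `record,ahi`), the input formats the pipeline readers
#' consume. Numbers are written with 17 significant digits so the files
#' round-trip bit-exactly through [read_rr_csv()].
#'
#' @param cohort output of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(cohort, function(rec) {
    path <- file.path(dir, sprintf("rr_%s.csv", rec$id))
    write_rr_csv(rec$rr, path)
    path
  }, character(1))
  ahi_path <- file.path(dir, "ahi.csv")
  ahi <- data.frame(record = vapply(cohort, `[[`, character(1), "id"),
                    ahi = vapply(cohort, `[[`, numeric(1), "ahi"))
  utils::write.csv(ahi, ahi_path, row.names = FALSE, quote = FALSE)
  invisible(c(paths, ahi_path))
}

#' Synthesize a single-lead ECG from known beat times
#'
#' Places a fixed QRS-like template (narrow positive R wave with small Q and S
#' deflections) at each beat time, then adds slow baseline wander and white
#' noise. Ground-truth beat times are retained in the returned record, so QRS
#' detectors can be scored exactly.
#'
#' @param beat_times strictly increasing beat times in seconds, no two closer
#'   than 200 ms.
#' @param fs sampling rate in Hz, >= 100.
#' @param noise_sd white-noise SD in units of the R-wave amplitude (~1.2);
#'   default 0.02.
#' @param wander_amp baseline-wander amplitude (default 0.1).
#' @param seed optional seed.
#' @return an `"ecg_record"`: `samples`, `fs`, `duration`, `truth_times`,
#'   `id`.
#' @export
synth_ecg <- function(beat_times, fs = 100, noise_sd = 0.02,
                      wander_amp = 0.1, seed = NULL) {
  if (length(beat_times) == 0) stop("empty beat list")
  if (any(diff(beat_times) < 0.2)) stop("overlapping beats: intervals < 200 ms")
  if (fs < 100) stop("sampling rate must be >= 100 Hz")
  if (!is.null(seed)) set.seed(seed)
  dur <- max(beat_times) + 0.5
  n <- ceiling(dur * fs)
  tt <- seq(-0.05, 0.05, by = 1 / fs)
  template <- 1.2 * exp(-(tt / 0.008)^2) -
    0.25 * exp(-((tt + 0.022) / 0.010)^2) -
    0.30 * exp(-((tt - 0.025) / 0.012)^2)
  half <- (length(template) - 1L) %/% 2L
  x <- numeric(n)
  centers <- round(beat_times * fs) + 1L
  for (c0 in centers) {
    lo <- c0 - half
    hi <- c0 + half
    src <- max(1L, lo):min(n, hi)
    x[src] <- x[src] + template[src - lo + 1L]
  }
  ts <- (seq_len(n) - 1L) / fs
  x <- x + wander_amp * sin(2 * pi * 0.3 * ts) +
    0.05 * sin(2 * pi * 0.05 * ts) +
    stats::rnorm(n, 0, noise_sd)
  structure(list(samples = x, fs = fs, duration = n / fs,
                 truth_times = beat_times, id = "synthetic"),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %.1f s at %g Hz (%d samples)\n",
              x$id, x$duration, x$fs, length(x$samples)))
  invisible(x)
}
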
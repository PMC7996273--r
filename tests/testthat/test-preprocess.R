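test_that("QRS detection recovers >= 99% of beats on synthetic ECG", {
  set.seed(5)
  rr <- synth_rr("N", cohort_spec(), duration_h = 5 / 60)$rr
  ecg <- synth_ecg(rr$beat_times, fs = 100, noise_sd = 0.06, seed = 9)
  peaks <- detect_r_peaks(ecg)
  det_t <- (peaks - 1) / ecg$fs
  hit <- vapply(ecg$truth_times,
                function(t) any(abs(det_t - t) <= 0.05), logical(1))
  expect_gte(mean(hit), 0.99)
  # false detections: at most 1% of detections unmatched to a true beat
  extra <- vapply(det_t,
                  function(t) all(abs(ecg$truth_times - t) > 0.05), logical(1))
  expect_lte(mean(extra), 0.01)
})

test_that("a 1 Hz template train yields RR of 1.000 s within one sample", {
  ecg <- synth_ecg(seq(0.5, 60, by = 1), fs = 100, noise_sd = 0,
                   wander_amp = 0, seed = 1)
  rr <- rr_from_peaks(detect_r_peaks(ecg), 100)
  expect_true(all(abs(rr$intervals - 1) <= 0.01 + 1e-12))
})

test_that("degenerate ECG input raises detection errors", {
  expect_error(detect_r_peaks(rep(0, 2000), 100), "flat")
  expect_error(detect_r_peaks(rnorm(300), 100), "too short")
  expect_error(detect_r_peaks(rnorm(2000), 50), ">= 100")
})

test_that("rr_from_peaks converts indices to seconds", {
  rr <- rr_from_peaks(c(0, 100, 200), 100)
  expect_equal(rr$intervals, c(1, 1))
  expect_equal(rr_from_peaks(c(0, 50), 100)$intervals, 0.5)
  expect_error(rr_from_peaks(c(10, 10, 20), 100), "strictly increasing")
  expect_error(rr_from_peaks(7, 100), "at least 2")
})

test_that("local median filter replaces outliers and rebuilds beat times", {
  clean <- new_rr_series_for_test(rep(1, 12))
  out <- correct_rr_local_median(clean)
  expect_equal(out$intervals, clean$intervals)
  expect_equal(sum(out$corrected), 0)

  spiky <- new_rr_series_for_test(c(rep(1, 5), 0.4, rep(1, 5)))
  fixed <- correct_rr_local_median(spiky, window = 5, tolerance = 0.2)
  expect_equal(fixed$intervals, rep(1, 11))
  expect_equal(sum(fixed$corrected), 1)
  expect_true(fixed$corrected[6])
  # beat times rebuilt from cumulative sums
  expect_equal(fixed$beat_times,
               c(spiky$beat_times[1], spiky$beat_times[1] + cumsum(fixed$intervals)))

  expect_error(correct_rr_local_median(spiky, window = 4), "odd")
})

test_that("injected spikes are flagged with few false alarms", {
  set.seed(20)
  n <- 600
  iv <- 1 + 0.03 * sin(2 * pi * 0.25 * cumsum(rep(1, n))) + rnorm(n, 0, 0.015)
  spike_at <- sample(3:(n - 2), 30)
  iv[spike_at] <- iv[spike_at] * sample(c(0.45, 1.8), 30, replace = TRUE)
  rr <- new_rr_series_for_test(iv)
  fixed <- correct_rr_local_median(rr)
  expect_true(all(fixed$corrected[spike_at]))
  false_flags <- setdiff(which(fixed$corrected), spike_at)
  expect_lt(length(false_flags) / n, 0.01)
})

test_that("minute segmentation uses half-open windows and conserves beats", {
  rr <- new_rr_series_for_test(rep(1, 6 * 3600))
  slices <- segment_minutes(rr)
  expect_length(slices, 360)
  expect_true(all(vapply(slices, `[[`, numeric(1), "n_beats") %in% 59:61))
  expect_true(all(vapply(slices, `[[`, logical(1), "valid")))
  # every tachogram point lands in exactly one minute
  expect_equal(sum(vapply(slices, `[[`, numeric(1), "n_beats")),
               sum(rr$beat_times[-1] < 360 * 60))

  # boundary beat at exactly t = 60 belongs to minute 1
  rr2 <- new_rr_series_for_test(c(30, 30))
  slices2 <- suppressWarnings(segment_minutes(rr2, hours = 1, min_beats = 1))
  expect_equal(slices2[[1]]$n_beats, 1)  # t = 30
  expect_equal(slices2[[2]]$n_beats, 1)  # t = 60 -> minute 1
  expect_equal(slices2[[2]]$times, 60)

  # short record: fewer segments plus a warning
  rr3 <- new_rr_series_for_test(rep(1, 3 * 3600 - 1))
  expect_warning(s3 <- segment_minutes(rr3), "180 of 360")
  expect_length(s3, 180)
})

test_that("2 Hz resampling yields 120 samples and reproduces simple shapes", {
  rr <- new_rr_series_for_test(rep(1, 70))
  sl <- segment_minutes(rr, hours = 1 / 60)[[1]]
  seg <- resample_2hz(sl)
  expect_length(seg$samples, 120)
  expect_true(all(abs(seg$samples - 1) < 1e-12))

  # tachogram linear in time: natural spline reproduces the line exactly
  times <- seq(0.5, 59.5, by = 1)
  sll <- structure(list(minute = 0, times = times,
                        intervals = 0.8 + 0.004 * times,
                        n_beats = length(times), valid = TRUE),
                   class = "rr_minute")
  segl <- resample_2hz(sll)
  grid <- seq(0, 59.5, 0.5)
  inside <- grid >= min(times) & grid <= max(times)
  expect_equal(segl$samples[inside], 0.8 + 0.004 * grid[inside],
               tolerance = 1e-6)

  # sinusoidal tachogram at 0.1 Hz keeps its dominant frequency
  t <- cumsum(rep(1, 70)); t <- t[t < 60]
  rrs <- new_rr_series_for_test(diff(c(0, t)))
  rrs$intervals <- 1 + 0.1 * sin(2 * pi * 0.1 * rrs$beat_times[-1])
  sls <- structure(list(minute = 0, times = rrs$beat_times[-1],
                        intervals = rrs$intervals,
                        n_beats = length(rrs$intervals), valid = TRUE),
                   class = "rr_minute")
  segs <- resample_2hz(sls)
  sp <- stats::spec.pgram(stats::ts(segs$samples, frequency = 2), plot = FALSE,
                          taper = 0, detrend = TRUE)
  expect_equal(sp$freq[which.max(sp$spec)], 0.1, tolerance = 0.03)

  # invalid slices propagate
  inval <- structure(list(minute = 0, times = 1:3, intervals = rep(1, 3),
                          n_beats = 3, valid = FALSE), class = "rr_minute")
  expect_false(resample_2hz(inval)$valid)
})

test_that("feature pipeline emits one row per minute with entropies and bands", {
  set.seed(2)
  rr <- synth_rr("N", cohort_spec(), duration_h = 0.1)$rr
  f <- rr_features(rr, hours = 0.1)
  expect_equal(nrow(f), 6)
  expect_true(all(f$valid))
  expect_true(all(is.finite(f$npsampen)))
  expect_true(all(is.finite(f$lf_hf)))
  expect_true(all(f$npsampen >= 0))
  # raw-interval entropy mode also works and differs from resampled mode
  f2 <- rr_features(rr, hours = 0.1, entropy_on = "raw")
  expect_true(all(is.finite(f2$npsampen)))
  expect_false(isTRUE(all.equal(f$npsampen, f2$npsampen)))
})

test_that("end-to-end ECG -> features recovers RR truth", {
  set.seed(77)
  rr <- synth_rr("N", cohort_spec(), duration_h = 2 / 60)$rr
  ecg <- synth_ecg(rr$beat_times, fs = 128, noise_sd = 0.05, seed = 8)
  peaks <- detect_r_peaks(ecg)
  det <- rr_from_peaks(peaks, 128)
  # filtering shifts every R peak by the same small offset, so compare the
  # intervals: match each detected beat to its nearest true beat and check
  # the implied RR against truth to within one sample period
  match_idx <- vapply(det$beat_times,
                      function(t) which.min(abs(ecg$truth_times - t)),
                      integer(1))
  ok <- diff(match_idx) == 1
  rr_true <- diff(ecg$truth_times)[match_idx[-length(match_idx)][ok]]
  rr_det <- det$intervals[ok]
  expect_gte(mean(abs(rr_det - rr_true) <= 1 / 128 + 1e-9), 0.99)
  expect_gte(mean(ok), 0.99)  # almost no missed/spurious beats
})
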
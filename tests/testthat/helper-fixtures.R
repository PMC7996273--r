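# build an rr_series directly from a vector of intervals (first beat at t0)
new_rr_series_for_test <- function(intervals, t0 = 0) {
  structure(list(beat_times = t0 + cumsum(c(0, intervals)),
                 intervals = intervals,
                 corrected = rep(FALSE, length(intervals))),
            class = "rr_series")
}

# recording-level aggregate table for a (possibly scaled-down) cohort
aggregate_cohort <- function(cohort, hours) {
  do.call(rbind, lapply(cohort, function(rec) {
    feats <- rr_features(rec$rr, hours = hours)
    cbind(data.frame(record = rec$id, ahi = rec$ahi, group = rec$group),
          aggregate_recording(feats))
  }))
}
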
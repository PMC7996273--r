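#' Read / write RR-interval CSV files
#'
#' The RR CSV format has a header and columns `time_s` (beat time in seconds,
#' the closing beat of each interval), `interval_s` and an optional integer
#' `flag` (1 = interval was median-corrected). [write_rr_csv()] prints 17
#' significant digits so values survive a round trip bit-exactly.
#'
#' @param path file path.
#' @return [read_rr_csv()]: an `"rr_series"`.
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "interval_s") %in% names(df))) {
    stop("RR CSV needs columns time_s, interval_s")
  }
  if (any(df$interval_s <= 0)) stop("intervals must be positive")
  corrected <- if ("flag" %in% names(df)) df$flag == 1L else
    rep(FALSE, nrow(df))
  # keep the stored intervals verbatim (recomputing them as time differences
  # would lose the last bits of precision)
  structure(list(beat_times = c(df$time_s[1] - df$interval_s[1], df$time_s),
                 intervals = df$interval_s, corrected = corrected),
            class = "rr_series")
}

#' @rdname read_rr_csv
#' @param rr an `"rr_series"`.
#' @export
write_rr_csv <- function(rr, path) {
  stopifnot(inherits(rr, "rr_series"))
  lines <- c("time_s,interval_s,flag",
             sprintf("%.17g,%.17g,%d", rr$beat_times[-1], rr$intervals,
                     as.integer(rr$corrected)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sampled-signal CSV as an ECG record
#'
#' One sample per line (no header, or a single-column header), with the
#' sampling rate supplied by the caller.
#'
#' @param path file path.
#' @param fs sampling rate in Hz.
#' @param id record identifier.
#' @return an `"ecg_record"`.
#' @export
read_signal_csv <- function(path, fs, id = basename(path)) {
  stopifnot(fs > 0)
  first <- readLines(path, n = 1)
  skip <- if (suppressWarnings(is.na(as.numeric(first)))) 1L else 0L
  x <- utils::read.csv(path, header = FALSE, skip = skip)[[1]]
  structure(list(samples = as.numeric(x), fs = fs, duration = length(x) / fs,
                 truth_times = NULL, id = id),
            class = "ecg_record")
}

#' Minimal WFDB record reader (formats 16 and 212)
#'
#' Optional loader for standard waveform-database records such as the
#' overnight apnea ECGs distributed by PhysioNet: parses the `.hea` header
#' and decodes the `.dat` signal file for the common storage formats 16
#' (little-endian 16-bit) and 212 (packed 12-bit pairs). Values are converted
#' to physical units as `(adc - baseline) / gain`.
#'
#' @param record path to the record without extension (i.e. `foo` for
#'   `foo.hea` + `foo.dat`).
#' @param channel 1-based signal index to extract (default 1).
#' @return an `"ecg_record"`.
#' @export
read_wfdb <- function(record, channel = 1) {
  hea <- paste0(record, ".hea")
  if (!file.exists(hea)) stop("header not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- top[1]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(sub("/.*$", "", top[3])) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  if (channel < 1 || channel > nsig) stop("channel out of range")
  sig <- strsplit(trimws(lines[1 + seq_len(nsig)]), "\\s+")
  parse_sig <- function(f) {
    gain_field <- if (length(f) >= 3) f[3] else "200"
    gain <- as.numeric(sub("^([-0-9.]+).*$", "\\1", gain_field))
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- if (grepl("\\(", gain_field)) {
      as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_field))
    } else if (length(f) >= 5) as.numeric(f[5]) else 0
    list(file = f[1], format = sub("x.*$", "", f[2]), gain = gain,
         baseline = baseline)
  }
  info <- lapply(sig, parse_sig)
  dat_files <- vapply(info, `[[`, character(1), "file")
  if (length(unique(dat_files)) != 1) {
    stop("multi-file records are not supported")
  }
  fmt <- info[[1]]$format
  dat <- file.path(dirname(hea), dat_files[1])
  raw_bytes <- readBin(dat, "raw", n = file.size(dat))
  adc <- switch(fmt,
    "16" = {
      v <- readBin(raw_bytes, "integer", n = length(raw_bytes) %/% 2,
                   size = 2, signed = TRUE, endian = "little")
      matrix(v, nrow = nsig)
    },
    "212" = {
      b <- as.integer(raw_bytes)
      nb <- (length(b) %/% 3) * 3
      b1 <- b[seq(1, nb, by = 3)]
      b2 <- b[seq(2, nb, by = 3)]
      b3 <- b[seq(3, nb, by = 3)]
      s1 <- bitwAnd(b2, 0x0FL) * 256L + b1
      s2 <- bitwAnd(b2, 0xF0L) * 16L + b3
      s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
      s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
      v <- as.vector(rbind(s1, s2))
      matrix(v, nrow = nsig)
    },
    stop(sprintf("unsupported WFDB format '%s' (only 16 and 212)", fmt)))
  x <- adc[channel, ]
  if (!is.na(nsamp) && nsamp > 0) x <- x[seq_len(min(nsamp, length(x)))]
  phys <- (x - info[[channel]]$baseline) / info[[channel]]$gain
  structure(list(samples = phys, fs = fs, duration = length(phys) / fs,
                 truth_times = NULL, id = name),
            class = "ecg_record")
}
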
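#' Generate a MIX(p) surrogate signal
#'
#' The MIX(p) process is a standard complexity benchmark: a deterministic
#' sine of period 12, `X_j = 2 sin(2 pi j / 12)` for `j = 1..N`, in which each
#' point is independently replaced, with probability `p`, by uniform noise
#' `Y_j ~ U(-3, 3)`:
#' `MIX(p)_j = (1 - Z_j) X_j + Z_j Y_j`, `Z_j ~ Bernoulli(p)`.
#' Complexity increases with `p`: `p = 0` is the pure sine, `p = 1` pure
#' noise.
#'
#' @param p replacement probability in `[0, 1]`.
#' @param n signal length (at least 10 points).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (this is how the sweep drivers advance one stream across
#'   replicates).
#' @return object of class `"mix_signal"`: list with `values` and the
#'   component realizations `x` (sine), `y` (noise), `z` (indicators), plus
#'   `p` and `n`.
#' @examples
#' s <- generate_mix(0.3, 100, seed = 7)
#' mean(s$z)  # close to 0.3
#' @export
generate_mix <- function(p, n, seed = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]")
  }
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 10 || n != round(n)) {
    stop("`n` must be an integer >= 10")
  }
  if (!is.null(seed)) set.seed(seed)
  j <- seq_len(n)
  x <- 2 * sin(2 * pi * j / 12)
  z <- stats::rbinom(n, 1L, p)
  y <- stats::runif(n, -3, 3)
  structure(list(values = (1 - z) * x + z * y, x = x, y = y, z = z,
                 p = p, n = n),
            class = "mix_signal")
}

mix_entropy <- function(values, method, m, r) {
  res <- switch(method,
                sampen = sampen(values, m = m, r = r),
                npsampen = npsampen(values, m = m),
                stop(sprintf("unknown method '%s'", method)))
  res$value
}

#' Entropy versus signal length on MIX(p) surrogates
#'
#' For every combination of replacement probability `p`, length `N` and
#' replicate, a fresh MIX signal is generated and the chosen entropy computed.
#' A single RNG stream (seeded once) drives the whole sweep, so the result is
#' reproducible from `seed` alone. Undefined SampEn values are recorded as
#' `NA`, never dropped.
#'
#' @param p_values numeric vector of replacement probabilities.
#' @param n_grid integer vector of signal lengths; default 50 to 200 in steps
#'   of 2 (the short-segment range of interest for 1-minute HRV).
#' @param reps replicates per (p, N) cell; default 1.
#' @param method `"npsampen"` (default) or `"sampen"`.
#' @param m embedding dimension.
#' @param r SampEn tolerance (multiple of SD); ignored for NPSampEn.
#' @param seed integer seed for the sweep stream.
#' @return a `"sweep_result"` data frame with columns `p`, `n`, `rep`,
#'   `value`.
#' @seealso [entropy_r_sweep()], [summarize_sweep()]
#' @export
entropy_length_sweep <- function(p_values, n_grid = seq(50, 200, by = 2),
                                 reps = 1, method = c("npsampen", "sampen"),
                                 m = 2, r = 0.25, seed = NULL) {
  method <- match.arg(method)
  stopifnot(reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(rep = seq_len(reps), n = n_grid, p = p_values,
                      KEEP.OUT.ATTRS = FALSE)
  # generation order: p outermost, then n, then replicate (expand.grid varies
  # its first factor fastest)
  value <- vapply(seq_len(nrow(grid)), function(i) {
    sig <- generate_mix(grid$p[i], grid$n[i])
    mix_entropy(sig$values, method, m, r)
  }, numeric(1))
  out <- data.frame(p = grid$p, n = grid$n, rep = grid$rep, value = value)
  attr(out, "method") <- method
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' SampEn versus tolerance r on MIX(p) surrogates
#'
#' One MIX signal is generated per (p, replicate); SampEn is then evaluated
#' over the whole tolerance grid on that signal (the template distances are
#' computed once and thresholded at each `r`). Cells where the estimator is
#' undefined (no matches at a small tolerance) are recorded as `NA`.
#'
#' @param p_values numeric vector of replacement probabilities.
#' @param n fixed signal length; default 100.
#' @param r_grid tolerances as multiples of the segment SD; default 0.1 to
#'   1.0 in steps of 0.02.
#' @param m embedding dimension.
#' @param reps replicates per p.
#' @param seed integer seed for the sweep stream.
#' @return a `"sweep_result"` data frame with columns `p`, `r`, `rep`,
#'   `value`.
#' @export
entropy_r_sweep <- function(p_values, n = 100, r_grid = seq(0.1, 1, by = 0.02),
                            m = 2, reps = 1, seed = NULL) {
  stopifnot(all(r_grid > 0), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (p in p_values) {
    for (rep_i in seq_len(reps)) {
      sig <- generate_mix(p, n)
      d <- template_distances(sig$values, m)
      value <- vapply(r_grid, function(r) {
        sampen(sig$values, m = m, r = r, distances = d)$value
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(p = p, r = r_grid, rep = rep_i, value = value)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "method") <- "sampen"
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Replicate mean and SD of a sweep
#'
#' @param sweep a `"sweep_result"` from [entropy_length_sweep()] or
#'   [entropy_r_sweep()].
#' @return data frame with one row per (p, grid point): replicate `mean`,
#'   `sd`, standard error `se`, and `n_defined` (replicates where the
#'   estimator was defined).
#' @export
summarize_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  gvar <- if ("n" %in% names(sweep)) "n" else "r"
  key <- interaction(sweep$p, sweep[[gvar]], drop = TRUE)
  agg <- do.call(rbind, lapply(split(sweep, key), function(g) {
    v <- g$value[!is.na(g$value)]
    data.frame(p = g$p[1], grid = g[[gvar]][1],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_defined = length(v))
  }))
  names(agg)[names(agg) == "grid"] <- gvar
  agg$se <- agg$sd / sqrt(pmax(agg$n_defined, 1))
  agg <- agg[order(agg$p, agg[[gvar]]), ]
  rownames(agg) <- NULL
  agg
}
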
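#' Population standard deviation
#'
#' Standard deviation with divisor `N` (not `N - 1`), the convention used for
#' the tolerance scaling of sample entropy.
#'
#' @param x numeric vector.
#' @return a single non-negative number.
#' @export
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Chebyshev template distance matrices at dimensions m and m + 1
#'
#' Embeds the series into template vectors
#' `X_i = (x(i), ..., x(i + m - 1))` and computes the pairwise Chebyshev
#' (maximum-coordinate) distance matrices `d^m` and `d^{m+1}`. Both matrices
#' are indexed over the same template range `i, j = 1 .. N - m`, so
#' `d^{m+1}[i, j] = max(d^m[i, j], |x(i + m) - x(j + m)|)` holds entrywise.
#' Self-matches are excluded: the diagonals are `NA`.
#'
#' @param x numeric series, all values finite.
#' @param m embedding dimension, a positive integer.
#' @return an object of class `"distance_pair"`: a list with square matrices
#'   `dm` and `dm1` (diagonal `NA`), the dimension `m`, and `n_templates =
#'   length(x) - m`.
#' @examples
#' d <- template_distances(sin(1:20), m = 2)
#' all(d$dm1 >= d$dm, na.rm = TRUE)
#' @export
template_distances <- function(x, m) {
  x <- as.numeric(x)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("`m` must be a positive integer")
  }
  if (any(!is.finite(x))) stop("series contains non-finite values")
  n <- length(x)
  if (n < m + 2) {
    stop(sprintf("series too short: need N >= %d for m = %d (got N = %d)",
                 m + 2, m, n))
  }
  nt <- n - m
  idx <- seq_len(nt)
  dm <- matrix(0, nt, nt)
  for (k in 0:(m - 1)) {
    xk <- x[idx + k]
    dm <- pmax(dm, abs(outer(xk, xk, "-")))
  }
  xm <- x[idx + m]
  dm1 <- pmax(dm, abs(outer(xm, xm, "-")))
  diag(dm) <- NA_real_
  diag(dm1) <- NA_real_
  structure(list(dm = dm, dm1 = dm1, m = m, n_templates = nt),
            class = "distance_pair")
}

off_diag <- function(mat) mat[!is.na(mat)]

#' Scope vector: the data-derived tolerance set
#'
#' Pools every off-diagonal entry of both distance matrices, deduplicates by
#' exact floating-point equality and sorts ascending. The resulting vector
#' plays the role of the full set of tolerance values that NPSampEn averages
#' over, replacing the single threshold `r` of classical sample entropy.
#'
#' @param d a `"distance_pair"` from [template_distances()].
#' @return an object of class `"scope_vector"`: list with the sorted unique
#'   distances `scope` and its length `nbin`.
#' @export
build_scope <- function(d) {
  stopifnot(inherits(d, "distance_pair"))
  scope <- sort(unique(c(off_diag(d$dm), off_diag(d$dm1))))
  structure(list(scope = scope, nbin = length(scope)), class = "scope_vector")
}

#' Cumulative match-probability profiles over the scope vector
#'
#' For each scope value `scope(q)` the profile `Phi^m(q)` is the average over
#' template rows `i` of the fraction of other templates `j` whose distance
#' `d^m_ij` does not exceed `scope(q)` — i.e. the mean row-wise empirical CDF
#' of the distance matrix evaluated at the scope points. Because every row has
#' the same number of off-diagonal entries, this equals the pooled empirical
#' CDF, which is how it is computed here.
#'
#' @param d a `"distance_pair"`.
#' @param scope a `"scope_vector"`, normally built from `d`.
#' @return list with numeric vectors `phi_m` and `phi_m1` (one entry per scope
#'   bin, nondecreasing, ending at 1) of class `"cumulative_profiles"`.
#' @export
cumulative_profiles <- function(d, scope) {
  stopifnot(inherits(d, "distance_pair"), inherits(scope, "scope_vector"))
  em <- sort(off_diag(d$dm))
  em1 <- sort(off_diag(d$dm1))
  phi_m <- findInterval(scope$scope, em) / length(em)
  phi_m1 <- findInterval(scope$scope, em1) / length(em1)
  structure(list(phi_m = phi_m, phi_m1 = phi_m1), class = "cumulative_profiles")
}

entropy_result <- function(value, method, diagnostics) {
  structure(list(value = value, method = method, diagnostics = diagnostics),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$method,
              if (is.na(x$value)) sprintf("undefined (%s)", x$diagnostics$reason)
              else format(x$value)))
  invisible(x)
}

#' Classical sample entropy
#'
#' `SampEn(m, r) = ln(Phi^m / Phi^{m+1})` where `Phi^m` is the probability
#' (self-matches excluded) that two templates of length `m` are within the
#' tolerance `r * SD(x)` in Chebyshev distance, and `Phi^{m+1}` the same at
#' length `m + 1`. `SD` is the population standard deviation of the segment.
#' When no template pair matches at dimension `m + 1` (or `m`) the statistic
#' is undefined; an `NA` value with a reason code is returned rather than an
#' error, so that batch sweeps can record the failure.
#'
#' @param x numeric series (length at least `m + 2`).
#' @param m embedding dimension; default 2.
#' @param r tolerance as a multiple of the segment standard deviation;
#'   default 0.2.
#' @param distances optional precomputed [template_distances()] result for
#'   `x` and `m` (avoids recomputation when several estimators share it).
#' @return an `"entropy_result"`: `value` (`NA` when undefined), `method`,
#'   and `diagnostics` (absolute tolerance, match counts, reason when
#'   undefined).
#' @seealso [npsampen()] for the tolerance-free variant.
#' @examples
#' sampen(rep(c(1, 2, 3), 4), m = 3, r = 0.5)$value  # 0: periodic signal
#' @export
sampen <- function(x, m = 2, r = 0.2, distances = NULL) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("`r` must be > 0")
  x <- as.numeric(x)
  d <- if (is.null(distances)) template_distances(x, m) else distances
  stopifnot(inherits(d, "distance_pair"))
  r_abs <- r * pop_sd(x)
  em <- off_diag(d$dm)
  em1 <- off_diag(d$dm1)
  b <- sum(em <= r_abs)   # ordered matching pairs at dimension m
  a <- sum(em1 <= r_abs)  # and at dimension m + 1
  phi_m <- b / length(em)
  phi_m1 <- a / length(em1)
  if (a == 0L || b == 0L) {
    return(entropy_result(NA_real_, "sampen", list(
      r = r, r_abs = r_abs, matches_m = b, matches_m1 = a,
      reason = "no template matches at this tolerance")))
  }
  entropy_result(log(phi_m / phi_m1), "sampen",
                 list(r = r, r_abs = r_abs, matches_m = b, matches_m1 = a))
}

#' Nonparametric sample entropy
#'
#' Tolerance-free sample entropy: instead of a single threshold, the sorted
#' unique template distances of the segment itself (the "scope" vector) are
#' used as tolerances, and the log-ratio of the two cumulative match
#' probability profiles is averaged over all scope bins:
#' `NPSampEn = mean_q ln(Phi^m(q) / Phi^{m+1}(q))`.
#'
#' Scope bins where `Phi^{m+1}(q) = 0` (typically the smallest distance,
#' which always originates from the dimension-`m` matrix) carry no defined
#' log-ratio; they are excluded from both the sum and the divisor, and their
#' count is reported in the diagnostics. Since the largest scope bin always
#' has `Phi^{m+1} = 1`, at least one bin contributes, so NPSampEn is defined
#' for every admissible series — including those where classical SampEn
#' degenerates at an ill-chosen `r`.
#'
#' The statistic is invariant under affine maps `x -> a * x + b` (`a != 0`)
#' and nonnegative by construction (`Phi^m >= Phi^{m+1}` entrywise).
#'
#' @inheritParams sampen
#' @return an `"entropy_result"` with diagnostics `nbin` (scope length) and
#'   `skipped_bins` (bins excluded for an empty `m + 1` profile).
#' @examples
#' set.seed(1)
#' npsampen(rnorm(60), m = 2)$value
#' @export
npsampen <- function(x, m = 2, distances = NULL) {
  x <- as.numeric(x)
  d <- if (is.null(distances)) template_distances(x, m) else distances
  stopifnot(inherits(d, "distance_pair"))
  scope <- build_scope(d)
  prof <- cumulative_profiles(d, scope)
  keep <- prof$phi_m1 > 0
  value <- mean(log(prof$phi_m[keep] / prof$phi_m1[keep]))
  entropy_result(value, "npsampen",
                 list(nbin = scope$nbin, skipped_bins = sum(!keep)))
}
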
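# Independent brute-force oracles, written as straight-line double loops so
# they share no code path with the package implementations.

oracle_distance_pair <- function(x, m) {
  n <- length(x)
  nt <- n - m
  dm <- matrix(NA_real_, nt, nt)
  dm1 <- matrix(NA_real_, nt, nt)
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      dmax <- 0
      for (k in 0:(m - 1)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
      dm[i, j] <- dmax
      dm1[i, j] <- max(dmax, abs(x[i + m] - x[j + m]))
    }
  }
  list(dm = dm, dm1 = dm1)
}

oracle_sampen <- function(x, m, r) {
  d <- oracle_distance_pair(x, m)
  r_abs <- r * sqrt(mean((x - mean(x))^2))
  cm <- sum(d$dm <= r_abs, na.rm = TRUE)
  cm1 <- sum(d$dm1 <= r_abs, na.rm = TRUE)
  if (cm == 0 || cm1 == 0) return(NA_real_)
  log(cm / cm1)
}

# row-wise CDF route of the nonparametric estimator (the package uses the
# pooled-count shortcut, so agreement checks the row-average identity too)
oracle_npsampen <- function(x, m) {
  d <- oracle_distance_pair(x, m)
  nt <- nrow(d$dm)
  scope <- sort(unique(c(d$dm[!is.na(d$dm)], d$dm1[!is.na(d$dm1)])))
  phi_m <- numeric(length(scope))
  phi_m1 <- numeric(length(scope))
  for (q in seq_along(scope)) {
    pm <- pm1 <- 0
    for (i in seq_len(nt)) {
      pm <- pm + mean(d$dm[i, -i] <= scope[q])
      pm1 <- pm1 + mean(d$dm1[i, -i] <= scope[q])
    }
    phi_m[q] <- pm / nt
    phi_m1[q] <- pm1 / nt
  }
  keep <- phi_m1 > 0
  mean(log(phi_m[keep] / phi_m1[keep]))
}

# exhaustive pair-counting AUC (ties count one half)
oracle_auc <- function(scores, positive_mask) {
  sp <- scores[positive_mask]
  sn <- scores[!positive_mask]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
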
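test_that("AHI thresholds assign severity groups with correct boundaries", {
  expect_equal(as.character(assign_group(c(0, 4.9, 5, 29.9, 30, 80))),
               c("N", "N", "MOSA", "MOSA", "SOSA", "SOSA"))
  expect_error(assign_group(-1), ">= 0")
})

test_that("recording aggregation averages valid minutes only", {
  tbl <- data.frame(minute = 0:3, valid = c(TRUE, FALSE, TRUE, FALSE),
                    n_beats = c(60, 10, 62, 5),
                    sampen = c(0.5, 9, 0.7, 9), npsampen = c(0.2, 9, 0.3, 9),
                    lf = c(1, 9, 3, 9), hf = c(2, 9, 2, 9),
                    lf_hf = c(0.5, 9, 1.5, 9))
  agg <- aggregate_recording(tbl)
  expect_equal(agg$npsampen, 0.25)
  expect_equal(agg$sampen, 0.6)
  expect_equal(agg$n_valid, 2)
  expect_equal(aggregate_recording(tbl[1, ])$npsampen, 0.2)
  expect_error(aggregate_recording(tbl[c(2, 4), ]), "no valid minutes")
})

test_that("confusion metrics implement the screening formulas", {
  m <- confusion_metrics(31, 19, 1, 9)
  expect_equal(round(m$acc, 1), 83.3)
  expect_equal(m$sen, 77.5)
  expect_equal(m$spe, 95.0)
  expect_equal(round(confusion_metrics(29, 12, 8, 11)$acc, 1), 68.3)
  # zero denominator yields an undefined marker, not an error
  u <- confusion_metrics(1, 0, 0, 0)
  expect_true(is.na(u$spe))
  expect_equal(u$acc, 100)
  expect_error(confusion_metrics(-1, 0, 0, 0), "nonnegative")
})

test_that("Fisher discriminant separates clusters and places a midpoint cut", {
  # well-separated 1-D clusters: perfect training accuracy
  x <- c(rnorm(20, 0, 0.1), rnorm(20, 5, 0.1))
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- fisher_discriminant(x, y)
  expect_equal(as.character(predict(fit, x)), as.character(y))

  # identical distributions: near-chance accuracy on fresh balanced data
  set.seed(4)
  x0 <- rnorm(400)
  y0 <- factor(rep(c("a", "b"), 200))
  fit0 <- fisher_discriminant(x0, y0)
  acc0 <- mean(predict(fit0, rnorm(400)) == factor(rep(c("a", "b"), 200)))
  expect_lt(abs(acc0 - 0.5), 0.12)

  # threshold within 10% of the analytic midpoint for Gaussian classes
  set.seed(10)
  xa <- rnorm(500, 0, 1); xb <- rnorm(500, 4, 1)
  fitg <- fisher_discriminant(c(xa, xb), factor(rep(c("a", "b"), each = 500)))
  grid <- seq(0, 4, by = 0.001)
  cls <- predict(fitg, grid)
  cut <- grid[max(which(cls == "a"))]
  midpoint <- (mean(xa) + mean(xb)) / 2
  expect_lt(abs(cut - midpoint), 0.1 * abs(midpoint))

  expect_error(fisher_discriminant(1:5, factor(rep("a", 5))), "2 classes")
})

test_that("stratified 2-fold nu-SVM screening behaves on edge datasets", {
  set.seed(6)
  # separable data
  x <- c(rnorm(20, 0, 0.2), rnorm(20, 6, 0.2))
  y <- factor(rep(c("neg", "pos"), each = 20))
  m <- svm_2fold(x, y, positive = "pos", seed = 3)
  expect_equal(m$acc, 100)
  # determinism under the same seed
  m2 <- svm_2fold(x, y, positive = "pos", seed = 3)
  expect_identical(unclass(m)[c("tp", "tn", "fp", "fn")],
                   unclass(m2)[c("tp", "tn", "fp", "fn")])
  # permuted labels on balanced data: near-chance accuracy
  set.seed(12)
  xr <- rnorm(200)
  yr <- factor(sample(rep(c("neg", "pos"), 100)))
  mr <- svm_2fold(xr, yr, positive = "pos", seed = 5)
  expect_lt(abs(mr$acc - 50), 15)
  expect_error(svm_2fold(rnorm(5), factor(c("a", "a", "a", "b", "b"))),
               "at least 4")
})

test_that("roc_auc matches the exhaustive pair-counting oracle", {
  # perfectly ranked
  expect_equal(roc_auc(1:10, factor(rep(c("n", "p"), each = 5)),
                       positive = "p"), 1)
  # all scores tied
  expect_equal(roc_auc(rep(1, 10), factor(rep(c("n", "p"), each = 5)),
                       positive = "p"), 0.5)
  # toy set with ties
  s <- c(0.1, 0.4, 0.35, 0.8, 0.4, 0.7)
  l <- factor(c("n", "n", "p", "p", "p", "n"))
  expect_equal(roc_auc(s, l, positive = "p"), oracle_auc(s, l == "p"))
  # random sets up to n = 50
  set.seed(30)
  for (i in 1:10) {
    n <- sample(6:50, 1)
    sc <- sample(round(rnorm(n), 1))  # rounding induces ties
    lb <- factor(sample(c("n", "p"), n, replace = TRUE,
                        prob = c(0.5, 0.5)))
    if (nlevels(droplevels(lb)) < 2) next
    expect_equal(roc_auc(sc, lb, positive = "p"), oracle_auc(sc, lb == "p"))
  }
  expect_error(roc_auc(1:4, factor(rep("p", 4))), "2 classes")
})

test_that("pearson_corr reproduces exact and sampled correlations", {
  x <- 1:20
  expect_equal(pearson_corr(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_corr(x, -x)$r, -1)
  set.seed(41)
  z <- MASS::mvrnorm(500, c(0, 0), matrix(c(1, 0.7, 0.7, 1), 2))
  est <- pearson_corr(z[, 1], z[, 2])
  expect_lt(abs(est$r - 0.7), 0.1)
  expect_lt(est$p, 1e-10)
  expect_error(pearson_corr(rep(1, 10), 1:10), "zero variance")
  expect_error(pearson_corr(1:2, 1:2), "n >= 3")
})

test_that("anova_lsd matches aov and flags the right pairs", {
  expect_error(anova_lsd(list(a = rep(1, 5), b = rep(1, 5))), "degenerate")

  # null simulation: type-I error rate of the F test near 5%
  set.seed(50)
  rejections <- 0
  for (i in 1:200) {
    g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
    if (anova_lsd(g)$p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections, 2)
  expect_lt(rejections, 25)

  # one shifted group: LSD flags exactly the two pairs involving it
  set.seed(51)
  g <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, 5))
  res <- anova_lsd(g)
  pw <- res$pairwise
  involving_c <- pw$group1 == "c" | pw$group2 == "c"
  expect_true(all(pw$p[involving_c] < 0.001))
  expect_true(all(pw$p[!involving_c] > 0.001))

  # LSD is never more conservative than Bonferroni-adjusted pairwise t
  bonf <- pmin(1, pw$p * nrow(pw))
  expect_true(all(pw$p <= bonf + 1e-15))

  # F and p agree with a direct aov fit
  y <- unlist(g); grp <- factor(rep(names(g), each = 30))
  ft <- summary(stats::aov(y ~ grp))[[1]]
  expect_equal(res$f, ft[["F value"]][1])
  expect_equal(res$p, ft[["Pr(>F)"]][1])
})

test_that("screen_recordings orients scores and reports coherent results", {
  set.seed(70)
  # synthetic recording-level table: entropy lower in apneic records
  n_n <- 15; n_a <- 25
  rec <- data.frame(
    npsampen = c(rnorm(n_n, 0.30, 0.01), rnorm(n_a, 0.22, 0.02)),
    ahi = c(runif(n_n, 0, 5), runif(n_a, 6, 70)))
  rep_ <- screen_recordings(rec, index = "npsampen", classifier = "fisher")
  expect_gt(rep_$metrics$acc, 90)
  expect_gt(rep_$auc, 0.9)   # orientation flip: low entropy = apneic
  expect_lt(rep_$pearson$r, -0.5)
  expect_s3_class(rep_$metrics, "screening_metrics")
  # SVM route is seeded and reproducible
  r1 <- screen_recordings(rec, index = "npsampen", classifier = "svm", seed = 2)
  r2 <- screen_recordings(rec, index = "npsampen", classifier = "svm", seed = 2)
  expect_equal(r1$metrics$acc, r2$metrics$acc)
})
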
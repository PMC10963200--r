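test_that("welch_t matches a direct Satterthwaite computation and edge cases", {
  x <- c(1, 2, 3)
  y <- c(1, 2, 3, 4, 5)
  # independent hand computation from the defining formulas
  se2 <- var(x) / 3 + var(y) / 5
  t_exp <- (mean(x) - mean(y)) / sqrt(se2)
  df_exp <- se2^2 / ((var(x) / 3)^2 / 2 + (var(y) / 5)^2 / 4)
  p_exp <- 2 * pt(-abs(t_exp), df_exp)
  got <- welch_t(x, y)
  expect_equal(got$t, t_exp, tolerance = 1e-10)
  expect_equal(got$p, p_exp, tolerance = 1e-10)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  set.seed(1)
  big <- welch_t(rnorm(2000, 0), rnorm(2000, 1))
  expect_lt(big$p, 1e-6)

  expect_error(welch_t(1, c(1, 2)), "insufficient")
})

test_that("pearson_r recovers exact and hand-computed correlations", {
  x <- c(2, 4, 6, 9)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:4, 1:5), "equal length")
})

test_that("chi-square / Cramer's V: perfect, null, and hand-computed tables", {
  perfect <- matrix(c(50, 0, 0, 50), 2)
  expect_equal(chisq_cramers_v(perfect)$v, 1)

  indep <- outer(c(20, 40), c(30, 10)) / 10 # rank-1 => exact independence
  res0 <- chisq_cramers_v(indep)
  expect_equal(res0$chi2, 0, tolerance = 1e-12)
  expect_equal(res0$v, 0, tolerance = 1e-8)

  tab <- matrix(c(30, 10, 10, 30), 2) # uncorrected chi2 = 20, V = 0.5
  res <- chisq_cramers_v(tab)
  expect_equal(res$chi2, 20)
  expect_equal(res$v, 0.5)

  # V invariant under row/column permutation
  expect_equal(chisq_cramers_v(tab[2:1, ])$v, res$v)
  expect_equal(chisq_cramers_v(tab[, 2:1])$v, res$v)

  expect_error(chisq_cramers_v(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("bh_adjust equals the exhaustive step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  set.seed(42)
  for (i in 1:25) {
    p <- round(runif(sample(1:20, 1)), 3)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("paired_t detects shifts and rejects degenerate differences", {
  set.seed(7)
  b <- rnorm(20)
  a <- b + 1 + rnorm(20, 0, 1e-3)
  res <- paired_t(a, b)
  expect_gt(res$t, 0)
  expect_lt(res$p, 1e-10)

  expect_error(paired_t(c(1, 2, 3), c(0, 1, 2)), "degenerate")

  # permuted labels: |t| small on average under the null
  set.seed(8)
  ts <- replicate(50, {
    x <- rnorm(30); y <- sample(x)
    abs(paired_t(x, y)$t)
  })
  expect_lt(median(ts), 2)
})

test_that("confusion_metrics reproduces hand arithmetic and identities", {
  pred <- c(rep(1, 4), rep(0, 6)) # tp 3, fp 1, tn 4, fn 2
  truth <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- confusion_metrics(pred, truth, positive = 1)
  expect_equal(m[c("tp", "fp", "tn", "fn")], list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$precision, 0.75)
  expect_equal(m$fdr, 0.25)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)

  ident <- confusion_metrics(truth, truth, positive = 1)
  expect_equal(unlist(ident[c("accuracy", "sensitivity", "specificity",
                              "precision", "f1")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 precision = 1, f1 = 1))
  expect_equal(ident$fdr, 0)

  flipped <- confusion_metrics(1 - truth, truth, positive = 1)
  expect_equal(flipped$accuracy, 0)
  expect_equal(flipped$sensitivity, 0)
  expect_equal(flipped$specificity, 0)

  # randomized identity checks: fdr + precision = 1, F1 harmonic identity
  set.seed(11)
  for (i in 1:20) {
    pr <- rbinom(40, 1, 0.5); tr <- rbinom(40, 1, 0.5)
    mm <- confusion_metrics(pr, tr, positive = 1)
    if (is.finite(mm$precision)) {
      expect_equal(mm$fdr + mm$precision, 1, tolerance = 1e-12)
    }
    if (is.finite(mm$f1)) {
      expect_equal(mm$f1,
                   2 * mm$precision * mm$sensitivity /
                     (mm$precision + mm$sensitivity),
                   tolerance = 1e-12)
    }
  }

  # zero-denominator ratios are flagged NaN, never silent zeros
  deg <- confusion_metrics(c(0, 0), c(0, 0), positive = 1)
  expect_true(is.nan(deg$sensitivity))
  expect_true(is.nan(deg$precision))
  expect_true(deg$degenerate)

  expect_error(confusion_metrics(c(1, 2, 3), c(1, 2, 3), positive = 1),
               "labels outside")
})

test_that("rank AUC equals trapezoidal ROC integration and is symmetric", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:5) {
    score <- rnorm(60)
    lab <- rbinom(60, 1, 0.5)
    if (length(unique(lab)) < 2) next
    a <- ionstim:::auc_rank(score, lab == 1)
    b <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                        direction = "<")))
    expect_equal(a, b, tolerance = 1e-10)
    expect_equal(ionstim:::auc_rank(-score, lab == 1), 1 - a,
                 tolerance = 1e-12)
  }
})
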
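test_that("diagnostic metrics reproduce the reader-study worked examples", {
  # CAP reader study, thick-slice arm: 38/50, 47/50, 38/41, 85/100
  m <- diagnostic_metrics(confusion_counts(tp = 38, fp = 3, tn = 47,
                                           fn = 12))
  expect_equal(unname(m$percent[c("accuracy", "sensitivity", "specificity",
                                  "precision", "f1")]),
               c(85.0, 76.0, 94.0, 92.7, 83.5))
  # same reader, synthetic thin-slice arm: 44/50, 49/50
  m <- diagnostic_metrics(confusion_counts(tp = 44, fp = 1, tn = 49,
                                           fn = 6))
  expect_equal(unname(m$percent["f1"]), 92.6)
  # perfect classifier
  m <- diagnostic_metrics(confusion_counts(10, 0, 10, 0))
  expect_true(all(m$percent == 100))
  # zero denominators flag rather than crash
  m <- diagnostic_metrics(confusion_counts(0, 0, 5, 0))
  expect_true("precision" %in% m$undefined)
  expect_true(is.na(m$percent["precision"]))
})

test_that("diagnostic metrics reproduce the AI-product worked examples", {
  # AI-assisted CAP diagnosis, thick-slice input: 83/145, 140/155, 83/98
  m <- diagnostic_metrics(confusion_counts(tp = 83, fp = 15, tn = 140,
                                           fn = 62))
  expect_equal(unname(m$percent[c("sensitivity", "specificity", "precision",
                                  "accuracy", "f1")]),
               c(57.2, 90.3, 84.7, 74.3, 68.3))
  # synthetic thin-slice input: 117/145, 140/155, 117/132
  m <- diagnostic_metrics(confusion_counts(tp = 117, fp = 15, tn = 140,
                                           fn = 28))
  expect_equal(unname(m$percent[c("sensitivity", "accuracy", "precision",
                                  "f1")]),
               c(80.7, 85.7, 88.6, 84.5))
})

test_that("McNemar exact branch matches binomial enumeration", {
  for (bc in list(c(10L, 0L), c(3L, 7L), c(5L, 5L), c(1L, 12L))) {
    res <- mcnemar_test(bc[1], bc[2])
    expect_equal(res$method, "exact-binomial")
    expect_equal(res$p, oracle_mcnemar(bc[1], bc[2]), tolerance = 1e-12)
    expect_equal(res$p, mcnemar_test(bc[2], bc[1])$p)  # symmetry
  }
  expect_equal(mcnemar_test(10, 0)$p, 2 * (1 / 2)^10)
  expect_gte(mcnemar_test(6, 6)$p, 0.99)
  res <- mcnemar_test(0, 0)
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
  # large-sample branch: chi-square with continuity correction
  res <- mcnemar_test(20, 10)
  expect_equal(res$method, "chi-square-cc")
  expect_equal(res$p,
               stats::mcnemar.test(matrix(c(0, 20, 10, 0), 2))$p.value)
})

test_that("DeLong AUC equals exhaustive pair counting", {
  set.seed(6)
  for (i in 1:5) {
    n <- sample(8:12, 1)
    labels <- c(rep(TRUE, 4), rep(FALSE, n - 4))
    a <- round(rnorm(n), 1)  # rounding forces some ties
    b <- round(rnorm(n), 1)
    res <- delong_auc_test(a, b, labels)
    expect_equal(res$auc_a, oracle_auc(a, labels), tolerance = 1e-12)
    expect_equal(res$auc_b, oracle_auc(b, labels), tolerance = 1e-12)
  }
  # perfectly separating scores
  lab <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  sc <- ifelse(lab, 2, 1)
  expect_equal(delong_auc_test(sc, sc + 0.1 * rnorm(6), lab)$auc_a, 1)
  # identical scores: zero difference, p = 1
  res <- delong_auc_test(sc, sc, lab)
  expect_equal(res$p, 1)
  expect_error(delong_auc_test(sc, sc, rep(TRUE, 6)), "both classes")
})

test_that("DeLong p-value agrees with pROC on a non-degenerate case", {
  set.seed(8)
  n <- 60
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  a <- rnorm(n, ifelse(labels, 1, 0))
  b <- 0.6 * a + rnorm(n, ifelse(labels, 0.4, 0))
  res <- delong_auc_test(a, b, labels)
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                        pROC::roc(labels, b, quiet = TRUE),
                        method = "delong", paired = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-9)
  expect_equal(res$auc_a, as.numeric(ref$estimate[1]), tolerance = 1e-12)
})

test_that("permutation test matches exhaustive swap enumeration", {
  truth <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  pred_a <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  pred_b <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  ex <- permutation_test_f1(pred_a, pred_b, truth, exact = TRUE)
  expect_equal(ex$p, oracle_permutation_f1(pred_a, pred_b, truth),
               tolerance = 1e-12)
  mc <- permutation_test_f1(pred_a, pred_b, truth, n_perm = 4000L,
                            seed = 2L)
  expect_equal(mc$p, ex$p, tolerance = 0.05)
  expect_identical(mc$p, permutation_test_f1(pred_a, pred_b, truth,
                                             n_perm = 4000L, seed = 2L)$p)
  # identical predictions give delta 0 and p = 1
  expect_equal(permutation_test_f1(pred_a, pred_a, truth, n_perm = 200L)$p,
               1)
  expect_equal(permutation_test_f1(pred_a, pred_b, truth, exact = TRUE,
                                   stat = "precision")$p,
               oracle_permutation_f1(pred_a, pred_b, truth, "precision"),
               tolerance = 1e-12)
})

test_that("Likert non-inferiority follows the one-sided shifted Wilcoxon", {
  set.seed(9)
  real <- sample(3:5, 20, replace = TRUE)
  # identical ratings: all shifted differences equal the margin, exact
  # one-sided p from all-positive tied ranks
  res <- likert_noninferiority(real, real, margin = 0.25)
  expect_equal(res$p, 2^-20, tolerance = 1e-12)
  expect_identical(res$verdict, "non-inferior")
  # uniformly one point worse: direction excludes non-inferiority
  worse <- pmax(real - 1L, 1L)
  res <- likert_noninferiority(real, worse, margin = 0.25)
  expect_identical(res$verdict, "not established")
  # zero margin with identical ratings is degenerate
  res <- likert_noninferiority(real, real, margin = 0)
  expect_true(res$degenerate)
})

test_that("diagnostic-quality rate comparison uses Yates chi-square", {
  # combined multi-reader counts: 634/640 real vs 407/640 bicubic
  res <- diagnostic_rate_chisq(c(634, 6), c(407, 233))
  expect_lt(res$p, 1e-10)
  expect_identical(res$method, "chi-square-yates")
  expect_equal(res$p, diagnostic_rate_chisq(c(407, 233), c(634, 6))$p)
  # identical proportions are not significant
  expect_gt(diagnostic_rate_chisq(c(50, 10), c(50, 10))$p, 0.95)
  # tiny expected cells fall back to the exact test
  res <- diagnostic_rate_chisq(c(3, 0), c(2, 1))
  expect_true(res$small_sample)
})

test_that("bootstrap CIs are seeded, degenerate-safe and well calibrated", {
  x <- rep(5.5, 20)
  ci <- bootstrap_ci(mean, x, n_boot = 200L, seed = 1L)
  expect_equal(unname(ci), c(5.5, 5.5))
  set.seed(10)
  y <- rnorm(50)
  expect_identical(bootstrap_ci(mean, y, n_boot = 300L, seed = 3L),
                   bootstrap_ci(mean, y, n_boot = 300L, seed = 3L))
  expect_error(bootstrap_ci(mean, numeric(0)), "empty")
  expect_error(bootstrap_ci(mean, y, n_boot = 10L), ">= 100")
  # coverage over simulated Bernoulli(0.7) datasets
  hits <- 0L
  for (s in 1:200) {
    d <- thinCT:::with_local_seed(1000L + s,
                                  stats::rbinom(60, 1, 0.7))
    ci <- bootstrap_ci(mean, d, n_boot = 400L, seed = s)
    if (ci["lo"] <= 0.7 && 0.7 <= ci["hi"]) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.90)
  expect_lte(hits / 200, 1.00)
})
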
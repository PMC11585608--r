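test_that("PSNR matches its closed forms and is monotone in noise", {
  a <- array(0.5, c(4, 16, 16))
  expect_identical(psnr(a, a), Inf)
  expect_equal(psnr(a, a + 0.01), 40)
  expect_equal(psnr(a, a - 0.1), 20)
  expect_equal(psnr(a, a + 0.01, data_range = 2), 40 + 20 * log10(2))
  set.seed(1)
  noise <- array(rnorm(length(a)), dim(a))
  vals <- vapply(c(0.005, 0.01, 0.02, 0.05), function(s)
    psnr(a, a + s * noise), 0)
  expect_true(all(diff(vals) < 0))
  expect_error(psnr(a, array(0.5, c(4, 16, 15))), "shapes")
})

test_that("SSIM closed forms: identity, luminance-only, symmetry", {
  set.seed(2)
  a <- array(runif(3 * 16 * 16), c(3, 16, 16))
  expect_equal(ssim(a, a), 1)
  # constant images: structure/contrast terms cancel, luminance remains
  mx <- 0.2; my <- 0.7
  x <- array(mx, c(1, 16, 16)); y <- array(my, c(1, 16, 16))
  expect_equal(ssim(x, y),
               (2 * mx * my + 1e-4) / (mx^2 + my^2 + 1e-4),
               tolerance = 1e-10)
  b <- array(runif(3 * 16 * 16), c(3, 16, 16))
  expect_equal(ssim(a, b), ssim(b, a))
  # invariant under a common permutation of slice order
  perm <- c(2, 3, 1)
  expect_equal(ssim(a[perm, , ], b[perm, , ]), ssim(a, b))
})

test_that("SSIM agrees with an independent reference implementation", {
  # frozen value computed with scikit-image 0.26 structural_similarity
  # (gaussian_weights=True, sigma=1.5, use_sample_covariance=False,
  # data_range=1) on the same deterministic slice
  set.seed(7)
  x <- matrix(runif(32 * 32), 32, 32)
  y <- pmin(pmax(x + matrix(rnorm(32 * 32, 0, 0.05), 32, 32), 0), 1)
  got <- ssim(array(x, c(1, 32, 32)), array(y, c(1, 32, 32)))
  expect_equal(got, 0.9855762, tolerance = 1e-6)
})

test_that("exact Wilcoxon branch agrees with full sign enumeration", {
  set.seed(3)
  for (n in c(5L, 8L, 10L, 12L)) {
    # include ties and zeros to exercise the tied-rank distribution
    d <- round(rnorm(n), if (n %% 2) 0 else 1)
    res <- thinCT:::wilcoxon_signed_rank(d, "two.sided")
    if (res$degenerate) next
    expect_equal(res$p, oracle_wilcoxon(d, "two.sided"),
                 tolerance = 1e-12, label = sprintf("n=%d", n))
    res1 <- thinCT:::wilcoxon_signed_rank(d, "greater")
    expect_equal(res1$p, oracle_wilcoxon(d, "greater"), tolerance = 1e-12)
  }
})

test_that("paired metric comparison applies the documented corrections", {
  a <- c(30.1, 31.4, 29.8, 33.0, 30.9, 31.7, 32.2, 29.5, 30.3, 31.1)
  # constant shift of +1 on n=10 pairs: exact two-sided p = 2 / 2^10
  res <- compare_paired_metrics(a, a + 1)
  expect_equal(res$p_raw, 2 / 2^10)
  expect_equal(compare_paired_metrics(a, a + 1, n_comparisons = 4)$p,
               4 * 2 / 2^10)
  # Bonferroni caps at 1
  set.seed(4)
  b <- a + rnorm(10, 0, 2)
  res <- compare_paired_metrics(a, b, n_comparisons = 50)
  expect_lte(res$p, 1)
  # all ties is degenerate with p = 1
  res <- compare_paired_metrics(a, a)
  expect_true(res$degenerate)
  expect_equal(res$p, 1)
})

test_that("large-sample Wilcoxon approximation tracks the exact branch", {
  set.seed(5)
  d <- rnorm(30, 0.3)
  approx <- thinCT:::wilcoxon_signed_rank(d, "two.sided", exact_max_n = 25L)
  exact <- thinCT:::wilcoxon_signed_rank(d, "two.sided", exact_max_n = 40L)
  expect_equal(approx$method, "normal-approximation")
  expect_equal(exact$method, "exact")
  expect_equal(approx$p, exact$p, tolerance = 0.15)
})

test_that("quality_report summarizes cohorts and compares methods", {
  ds <- make_paired_dataset(3, phantom_config(shape_thin = c(21L, 24L, 24L)),
                            seed = 51L)
  refs <- lapply(ds, `[[`, "thin")
  bis <- lapply(ds, function(s) bicubic_baseline(s$thick))
  # a deliberately worse "method": nearest-slice replication
  worse <- lapply(ds, function(s) {
    arr <- s$thick$values[rep(seq_len(dim(s$thick$values)[1]),
                              times = c(rep(5, dim(s$thick$values)[1] - 1),
                                        1)), , ]
    ct_volume(arr, spacing = c(1, s$thick$spacing[2:3]))
  })
  rep <- quality_report(refs, bis, worse)
  expect_named(rep$summary,
               c("psnr_dls", "ssim_dls", "psnr_bis", "ssim_bis"))
  expect_gt(rep$summary$psnr_dls["median"], rep$summary$psnr_bis["median"])
  expect_true(all(rep$per_case$ssim_dls <= 1))
  expect_lte(rep$p_values$psnr, 1)
})
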
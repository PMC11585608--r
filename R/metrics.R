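#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` over all voxels; `Inf` when the inputs
#' are identical.  Metrics are computed in normalized `[0, 1]` space by
#' default (`data_range = 1`), matching the model's training space.
#'
#' @param ref,test numeric arrays or `ct_volume`s of identical shape.
#' @param data_range intensity range of the data.
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, data_range = 1.0) {
  a <- if (is_ct_volume(ref)) ref$values else ref
  b <- if (is_ct_volume(test)) test$values else test
  if (!identical(dim(a), dim(b)))
    stop("psnr: shapes differ")
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(data_range^2 / mse)
}

# separable valid-mode Gaussian window moments for one slice
.ssim_kernel <- function(n, win = 11L, sigma = 1.5) {
  half <- (win - 1L) %/% 2L
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  K <- matrix(0, n - win + 1L, n)
  for (i in seq_len(nrow(K))) K[i, i:(i + win - 1L)] <- k
  K
}

#' Structural similarity index
#'
#' 2-D SSIM per axial slice with an 11x11 Gaussian window (sigma 1.5),
#' `K1 = 0.01`, `K2 = 0.03`, data range 1, computed in valid mode (window
#' fully inside the slice); the volume score is the mean over slices of
#' the mean local SSIM.
#'
#' @inheritParams psnr
#' @return SSIM in `[-1, 1]` (1 for identical volumes).
#' @export
ssim <- function(ref, test, data_range = 1.0) {
  a <- if (is_ct_volume(ref)) ref$values else ref
  b <- if (is_ct_volume(test)) test$values else test
  if (!identical(dim(a), dim(b)))
    stop("ssim: shapes differ")
  d <- dim(a)
  if (d[2] < 11L || d[3] < 11L)
    stop("ssim: in-plane extent must be >= the 11x11 window")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  KH <- .ssim_kernel(d[2]); KW <- .ssim_kernel(d[3])
  smooth <- function(m) KH %*% m %*% t(KW)
  mean(vapply(seq_len(d[1]), function(z) {
    x <- a[z, , ]; y <- b[z, , ]
    mx <- smooth(x); my <- smooth(y)
    vx <- smooth(x * x) - mx^2
    vy <- smooth(y * y) - my^2
    cxy <- smooth(x * y) - mx * my
    mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
           ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }, 0))
}

# ---- Wilcoxon signed-rank with exact tied-rank distribution ---------------

# Exact null distribution of W+ (sum of positive signed ranks, average
# ranks on ties) via the generating-function convolution over doubled
# ranks; returns P(W+ <= w) and P(W+ >= w).
wsr_exact_tail <- function(ranks2, w2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1] <- 1
  for (rk in ranks2) {
    g <- f
    g[(rk + 1L):(total + 1L)] <- g[(rk + 1L):(total + 1L)] +
      f[seq_len(total + 1L - rk)]
    f <- g
  }
  tot <- sum(f)
  list(p_le = sum(f[seq_len(w2 + 1L)]) / tot,
       p_ge = sum(f[(w2 + 1L):(total + 1L)]) / tot)
}

# core signed-rank test; alternative "two.sided" or "greater"
wilcoxon_signed_rank <- function(d, alternative = c("two.sided", "greater"),
                                 exact_max_n = 25L) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p = 1, statistic = NA_real_, n = 0L, degenerate = TRUE,
                method = "degenerate"))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= exact_max_n) {
    ranks2 <- as.integer(round(2 * rk))
    tails <- wsr_exact_tail(ranks2, as.integer(round(2 * W)))
    p <- switch(alternative,
                greater = tails$p_ge,
                two.sided = min(1, 2 * min(tails$p_le, tails$p_ge)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sig2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                two.sided = 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(p = p, statistic = W, n = n, degenerate = FALSE, method = method)
}

#' Paired comparison of per-case metrics with Bonferroni correction
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences
#' `b - a` (zero differences dropped, average ranks on ties; exact tied
#' distribution for n <= 25, normal approximation with continuity and tie
#' correction above), with the p-value multiplied by `n_comparisons` and
#' capped at 1.
#'
#' @param a,b equal-length numeric vectors of per-case values.
#' @param n_comparisons number of pairwise comparisons in the family.
#' @return List with `p` (corrected), `p_raw`, `statistic`, `n`,
#'   `degenerate` and `method`.
#' @export
compare_paired_metrics <- function(a, b, n_comparisons = 1L) {
  if (length(a) != length(b)) stop("compare_paired_metrics: lengths differ")
  res <- wilcoxon_signed_rank(b - a, "two.sided")
  res$p_raw <- res$p
  res$p <- min(1, res$p * n_comparisons)
  res
}

#' Per-cohort image-quality report
#'
#' Computes per-case PSNR and SSIM of two synthesis methods against the
#' reference thin volumes (in normalized space), their medians and IQRs,
#' and the paired Wilcoxon comparisons between the methods.
#'
#' @param refs,dls,bis lists of `ct_volume`s of equal length and geometry.
#' @param n_comparisons Bonferroni family size for the reported p-values.
#' @return A `quality_report` list with `per_case` (data.frame), `summary`
#'   (medians and IQRs) and `p_values`.
#' @export
quality_report <- function(refs, dls, bis, n_comparisons = 1L) {
  stopifnot(length(refs) == length(dls), length(refs) == length(bis))
  met <- function(ref, test) {
    rn <- normalize_hu(ref); tn <- normalize_hu(test)
    c(psnr = psnr(rn, tn), ssim = ssim(rn, tn))
  }
  md <- t(vapply(seq_along(refs), function(i) met(refs[[i]], dls[[i]]),
                 c(psnr = 0, ssim = 0)))
  mb <- t(vapply(seq_along(refs), function(i) met(refs[[i]], bis[[i]]),
                 c(psnr = 0, ssim = 0)))
  per_case <- data.frame(case = seq_along(refs),
                         psnr_dls = md[, "psnr"], ssim_dls = md[, "ssim"],
                         psnr_bis = mb[, "psnr"], ssim_bis = mb[, "ssim"])
  qsum <- function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    c(median = q[2], iqr_lo = q[1], iqr_hi = q[3])
  }
  structure(list(
    per_case = per_case,
    summary = list(psnr_dls = qsum(per_case$psnr_dls),
                   ssim_dls = qsum(per_case$ssim_dls),
                   psnr_bis = qsum(per_case$psnr_bis),
                   ssim_bis = qsum(per_case$ssim_bis)),
    p_values = list(
      psnr = compare_paired_metrics(per_case$psnr_bis, per_case$psnr_dls,
                                    n_comparisons)$p,
      ssim = compare_paired_metrics(per_case$ssim_bis, per_case$ssim_dls,
                                    n_comparisons)$p)),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality_report>\n")
  for (nm in names(x$summary)) {
    s <- x$summary[[nm]]
    cat(sprintf("  %-9s median %.4g [IQR %.4g-%.4g]\n", nm, s["median"],
                s["iqr_lo"], s["iqr_hi"]))
  }
  cat(sprintf("  Wilcoxon DLS vs BIS: PSNR p = %.3g, SSIM p = %.3g\n",
              x$p_values$psnr, x$p_values$ssim))
  invisible(x)
}
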
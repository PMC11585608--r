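#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v)))
    stop("confusion counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

# round half away from zero to one decimal, matching table presentation
round1_away <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10

#' Diagnostic accuracy metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, precision and F1-score on the
#' 0-100 scale, rounded to one decimal (half away from zero) as reported
#' in diagnostic-accuracy tables.  A metric whose denominator is zero is
#' returned as `NA` and listed in `undefined` rather than raising an
#' error.
#'
#' @param counts a [confusion_counts()].
#' @return List with `percent` (named, one decimal), `raw` (unrounded
#'   proportions in `[0, 1]`; F1 also in `[0, 1]`) and `undefined`
#'   (character vector).
#' @export
diagnostic_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  num <- c(accuracy = tp + tn, sensitivity = tp, specificity = tn,
           precision = tp)
  den <- c(accuracy = tp + fp + tn + fn, sensitivity = tp + fn,
           specificity = tn + fp, precision = tp + fp)
  raw <- ifelse(den > 0, num / den, NA_real_)
  f1 <- if (!is.na(raw["precision"]) && !is.na(raw["sensitivity"]) &&
            (raw["precision"] + raw["sensitivity"]) > 0)
    2 * raw["precision"] * raw["sensitivity"] /
      (raw["precision"] + raw["sensitivity"])
  else NA_real_
  raw <- c(raw, f1 = unname(f1))
  list(percent = round1_away(100 * raw), raw = raw,
       undefined = names(raw)[is.na(raw)])
}

#' McNemar test for paired proportions
#'
#' Exact two-sided binomial test on the discordant pairs when
#' `b + c < 25`, chi-square with continuity correction otherwise.
#'
#' @param b,c discordant counts.
#' @return List with `p`, `method` and `degenerate`.
#' @export
mcnemar_test <- function(b, c) {
  stopifnot(b >= 0, c >= 0)
  n <- b + c
  if (n == 0)
    return(list(p = 1, method = "degenerate", degenerate = TRUE))
  if (n < 25) {
    p <- stats::binom.test(b, n, p = 0.5)$p.value
    method <- "exact-binomial"
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi-square-cc"
  }
  list(p = min(1, p), method = method, degenerate = FALSE)
}

# AUC by Mann-Whitney pair counting plus DeLong placement components
delong_placements <- function(scores, labels) {
  x <- scores[labels]   # positives
  y <- scores[!labels]  # negatives
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi),
       m = m, n = n)
}

#' Paired DeLong test for comparing two AUCs
#'
#' AUCs are computed by Mann-Whitney pair counting (ties count 1/2); the
#' variance of the AUC difference uses the DeLong placement-value
#' covariance for paired designs, and a two-sided normal p-value is
#' returned.
#'
#' @param scores_a,scores_b numeric scores of the two methods on the same
#'   cases.
#' @param labels logical (or 0/1) true class per case; both classes must
#'   be present.
#' @return List with `auc_a`, `auc_b`, `p`, `var_diff`, `degenerate`.
#' @export
delong_auc_test <- function(scores_a, scores_b, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("delong_auc_test: both classes must be present")
  if (length(scores_a) != length(labels) ||
      length(scores_b) != length(labels))
    stop("delong_auc_test: lengths differ")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  d <- pa$auc - pb$auc
  if (var_diff <= 0 || !is.finite(var_diff)) {
    p <- if (d == 0) 1 else 0
    return(list(auc_a = pa$auc, auc_b = pb$auc, p = p, var_diff = var_diff,
                degenerate = TRUE))
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, p = 2 * stats::pnorm(-abs(z)),
       var_diff = var_diff, degenerate = FALSE)
}

# F1 / precision from binary predictions against truth (0 when undefined)
binary_stat <- function(pred, truth, stat) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  sens <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (stat == "precision") return(prec)
  if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
}

#' Permutation test for paired precision / F1 differences
#'
#' The null distribution is built by independently swapping the two
#' methods' predictions per case; the p-value is
#' `(1 + #(|stat_perm| >= |stat_obs|)) / (1 + n_perm)`, seeded and
#' reproducible.  With `exact = TRUE` all `2^n` swap patterns are
#' enumerated (n <= 20) and the p-value is the exact proportion.
#'
#' @param pred_a,pred_b logical (or 0/1) predictions of the two methods.
#' @param truth logical true labels.
#' @param n_perm number of random permutations.
#' @param seed integer seed.
#' @param stat `"f1"` or `"precision"`.
#' @param exact enumerate all swap patterns instead of sampling.
#' @return List with `p`, `delta_obs`, `n_perm`, `method`.
#' @export
permutation_test_f1 <- function(pred_a, pred_b, truth, n_perm = 10000L,
                                seed = 1L, stat = c("f1", "precision"),
                                exact = FALSE) {
  stat <- match.arg(stat)
  pred_a <- as.logical(pred_a); pred_b <- as.logical(pred_b)
  truth <- as.logical(truth)
  n <- length(truth)
  if (length(pred_a) != n || length(pred_b) != n)
    stop("permutation_test_f1: lengths differ")
  if (!exact && n_perm < 1) stop("permutation_test_f1: n_perm must be >= 1")
  obs <- binary_stat(pred_a, truth, stat) - binary_stat(pred_b, truth, stat)
  if (exact) {
    if (n > 20L) stop("permutation_test_f1: exact enumeration needs n <= 20")
    cnt <- 0L
    for (mask in 0:(2^n - 1)) {
      sw <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
      a2 <- ifelse(sw, pred_b, pred_a)
      b2 <- ifelse(sw, pred_a, pred_b)
      d <- binary_stat(a2, truth, stat) - binary_stat(b2, truth, stat)
      if (abs(d) >= abs(obs) - 1e-12) cnt <- cnt + 1L
    }
    return(list(p = cnt / 2^n, delta_obs = obs, n_perm = 2^n,
                method = "exact-enumeration"))
  }
  cnt <- with_local_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      sw <- stats::runif(n) < 0.5
      a2 <- ifelse(sw, pred_b, pred_a)
      b2 <- ifelse(sw, pred_a, pred_b)
      d <- binary_stat(a2, truth, stat) - binary_stat(b2, truth, stat)
      if (abs(d) >= abs(obs) - 1e-12) hits <- hits + 1L
    }
    hits
  })
  list(p = (1 + cnt) / (1 + n_perm), delta_obs = obs,
       n_perm = as.integer(n_perm), method = "monte-carlo")
}

#' One-sided Wilcoxon non-inferiority test for paired Likert ratings
#'
#' Tests whether synthetic image quality is non-inferior to real within a
#' margin: on `d_i = synth_i - real_i + margin`, a one-sided Wilcoxon
#' signed-rank test of H0 (median shift <= 0) against H1 (> 0).  The
#' verdict is `"non-inferior"` when `p < alpha`.
#'
#' @param real,synth integer Likert scores in 1..5, paired.
#' @param margin non-inferiority margin in points.
#' @param alpha significance level.
#' @return List with `p`, `verdict`, `degenerate`, `n`.
#' @export
likert_noninferiority <- function(real, synth, margin = 0.25,
                                  alpha = 0.05) {
  if (length(real) != length(synth))
    stop("likert_noninferiority: lengths differ")
  if (!all(c(real, synth) %in% 1:5))
    stop("likert_noninferiority: scores must be integers in 1..5")
  d <- synth - real + margin
  res <- wilcoxon_signed_rank(d, "greater")
  if (res$degenerate)
    return(list(p = NA_real_, verdict = "degenerate", degenerate = TRUE,
                n = 0L))
  list(p = res$p,
       verdict = if (res$p < alpha) "non-inferior" else "not established",
       degenerate = FALSE, n = res$n)
}

#' Chi-square comparison of diagnostic-quality rates
#'
#' 2x2 chi-square with Yates continuity correction on
#' (diagnostic, nondiagnostic) counts of two image types; falls back to
#' Fisher's exact test (flagged) when any expected cell is below 1.
#'
#' @param counts_a,counts_b length-2 vectors `(diagnostic, nondiagnostic)`.
#' @return List with `p`, `method`, `small_sample`.
#' @export
diagnostic_rate_chisq <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 2, length(counts_b) == 2,
            sum(counts_a) > 0, sum(counts_b) > 0)
  tab <- rbind(a = counts_a, b = counts_b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    p <- stats::fisher.test(tab)$p.value
    return(list(p = p, method = "fisher-exact", small_sample = TRUE))
  }
  p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
  list(p = p, method = "chi-square-yates", small_sample = FALSE)
}

#' Percentile bootstrap confidence interval
#'
#' Seeded resampling with replacement; returns the 2.5/97.5 percentile
#' bounds (for `conf = 0.95`) of the statistic over `n_boot` resamples.
#'
#' @param stat_fn function of a data vector (or data.frame) returning a
#'   scalar.
#' @param data numeric vector or data.frame (resampled by row).
#' @param n_boot number of bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return Named numeric `c(lo, hi)`.
#' @export
bootstrap_ci <- function(stat_fn, data, n_boot = 2000L, seed = 1L,
                         conf = 0.95) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n == 0) stop("bootstrap_ci: empty data")
  if (n_boot < 100) stop("bootstrap_ci: n_boot must be >= 100")
  stats_v <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      stat_fn(if (is.data.frame(data)) data[idx, , drop = FALSE]
              else data[idx])
    }, 0)
  })
  q <- stats::quantile(stats_v, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       names = FALSE)
  c(lo = q[1], hi = q[2])
}
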
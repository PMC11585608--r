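# Independent brute-force oracles used to validate the analytic
# implementations on small inputs.

# Wilcoxon signed-rank p-value by full enumeration of all 2^n sign
# assignments (zeros already dropped by the caller).
oracle_wilcoxon <- function(d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  Ws <- vapply(0:(2^n - 1), function(mask) {
    pos <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    sum(rk[pos])
  }, 0)
  eps <- 1e-9
  p_ge <- mean(Ws >= W - eps)
  p_le <- mean(Ws <= W + eps)
  if (alternative == "greater") p_ge else min(1, 2 * min(p_le, p_ge))
}

# exact two-sided McNemar p by binomial pmf enumeration
oracle_mcnemar <- function(b, c) {
  n <- b + c
  pmf <- stats::dbinom(0:n, n, 0.5)
  sum(pmf[pmf <= pmf[b + 1] + 1e-12])
}

# AUC by exhaustive pair counting (ties count 1/2)
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (x in pos) for (y in neg) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# brute-force slice-profile degradation: plain mean over the truncated
# centered window, one output voxel at a time
oracle_degrade_box <- function(arr, r) {
  D <- dim(arr)[1]
  Dk <- (D - 1) %/% r + 1
  half <- r %/% 2
  out <- array(0, c(Dk, dim(arr)[2], dim(arr)[3]))
  for (i in seq_len(Dk)) for (y in seq_len(dim(arr)[2]))
    for (x in seq_len(dim(arr)[3])) {
      zc <- (i - 1) * r + 1
      zz <- (zc - half):(zc + half)
      zz <- zz[zz >= 1 & zz <= D]
      out[i, y, x] <- mean(arr[zz, y, x])
    }
  out
}

# exhaustive permutation test over all 2^n swap patterns
oracle_permutation_f1 <- function(pred_a, pred_b, truth, stat = "f1") {
  f <- function(p, t) {
    tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (stat == "precision") return(prec)
    if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  }
  n <- length(truth)
  obs <- f(pred_a, truth) - f(pred_b, truth)
  ds <- vapply(0:(2^n - 1), function(mask) {
    sw <- as.logical(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L))
    f(ifelse(sw, pred_b, pred_a), truth) - f(ifelse(sw, pred_a, pred_b), truth)
  }, 0)
  mean(abs(ds) >= abs(obs) - 1e-12)
}

# a small deterministic HU test volume with structure along every axis
tiny_volume <- function(D = 11L, H = 16L, W = 16L, seed = 42L) {
  set.seed(seed)
  arr <- array(stats::rnorm(D * H * W, -500, 300), c(D, H, W))
  arr <- pmin(pmax(arr, -1024), 2048)
  ct_volume(arr, spacing = c(1, 0.7, 0.7), origin = c(3, -10, 2.5))
}
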
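#' Training configuration
#'
#' Defaults follow the optimization protocol used at full scale: AdamW
#' with initial learning rate 3e-4 and weight decay 1e-4, mini-batch 1, at
#' most 2000 epochs, validation PSNR evaluated every 5 epochs, learning
#' rate divided by 10 after 3 consecutive non-improving evaluations, and
#' training stopped after 3 reductions.  The crop defaults to the
#' full-scale `(8, 256, 256)` training cube; desk-scale runs pass a
#' smaller crop.
#'
#' @param lr0 initial learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param batch_size mini-batch size (the protocol uses 1).
#' @param max_epochs maximum epochs.
#' @param eval_every validation cadence in epochs.
#' @param patience consecutive non-improving evaluations per LR drop.
#' @param lr_drop_factor multiplicative LR factor at each drop.
#' @param max_drops stop after this many drops.
#' @param seed seed covering crop sampling and flip decisions.
#' @param crop `(L, H, W)` thick-space crop.
#' @param augment apply random crop + horizontal flip.
#' @param loss `"l1"` (default) or `"l2"`.
#' @param betas,eps AdamW moment coefficients and epsilon.
#' @param min_crop_sd structure-weighted crop sampling: when positive,
#'   up to 12 candidate crops are drawn and the first whose thick-cube
#'   standard deviation (normalized units) reaches this threshold is
#'   kept (the most-structured candidate otherwise).  Concentrates the
#'   few optimizer steps of short runs on informative regions; 0
#'   disables it.
#' @param grad_clip global gradient-norm clipping threshold applied
#'   before each AdamW step (`Inf` disables; short high-learning-rate
#'   runs use 1).
#' @param val_crop `(L, H, W)` center-crop size used for validation
#'   PSNR; defaults to `crop`.  A larger validation crop reduces the
#'   variance of checkpoint selection.
#' @return A `train_config` list.
#' @export
train_config <- function(lr0 = 3e-4, weight_decay = 1e-4, batch_size = 1L,
                         max_epochs = 2000L, eval_every = 5L, patience = 3L,
                         lr_drop_factor = 0.1, max_drops = 3L, seed = 1L,
                         crop = c(8L, 256L, 256L), augment = TRUE,
                         loss = c("l1", "l2"), betas = c(0.9, 0.999),
                         eps = 1e-8, min_crop_sd = 0, grad_clip = Inf,
                         val_crop = NULL) {
  loss <- match.arg(loss)
  stopifnot(lr0 > 0, eval_every >= 1, patience >= 1, max_drops >= 1,
            length(crop) == 3)
  structure(list(lr0 = lr0, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 eval_every = as.integer(eval_every),
                 patience = as.integer(patience),
                 lr_drop_factor = lr_drop_factor,
                 max_drops = as.integer(max_drops), seed = as.integer(seed),
                 crop = as.integer(crop), augment = isTRUE(augment),
                 loss = loss, betas = betas, eps = eps,
                 min_crop_sd = min_crop_sd, grad_clip = grad_clip,
                 val_crop = if (is.null(val_crop)) NULL
                            else as.integer(val_crop)),
            class = "train_config")
}

#' Sample an aligned thick/thin training cube from a paired sample
#'
#' A thick crop starting at axial index `i` (0-based) is paired with the
#' thin crop starting at `r*i`, preserving the coincident-slice
#' alignment; in-plane crops use identical `(y, x)` offsets on both
#' volumes.  With `cfg$augment`, the crop position is uniform and a
#' horizontal (x-axis) flip is applied to both cubes with probability 0.5;
#' otherwise the center crop is taken.  Intensities are normalized to
#' `[0, 1]`.  Randomness is drawn from the current RNG stream.
#'
#' @param sample a paired sample (list with `thin`, `thick`, `r`).
#' @param cfg a [train_config()].
#' @return List with `thick` `(L, h, w)`, `thin` `((L-1)r+1, h, w)`,
#'   1-based start indices `z0, y0, x0` (thick space) and `flipped`.
#' @export
sample_training_cube <- function(sample, cfg) {
  r <- sample$r
  dk <- dim(sample$thick$values)
  L <- cfg$crop[1]; h <- cfg$crop[2]; w <- cfg$crop[3]
  if (dk[1] < L || dk[2] < h || dk[3] < w)
    stop(sprintf(
      "sample_training_cube: volume %dx%dx%d smaller than crop %dx%dx%d",
      dk[1], dk[2], dk[3], L, h, w))
  pick <- function(extent, size, center) {
    if (extent == size) return(1L)
    if (center) return(1L + (extent - size) %/% 2L)
    sample.int(extent - size + 1L, 1L)
  }
  kv <- normalize_hu(sample$thick)$values
  nv <- normalize_hu(sample$thin)$values
  tries <- if (cfg$augment && cfg$min_crop_sd > 0) 12L else 1L
  best <- NULL
  for (t in seq_len(tries)) {
    z0 <- pick(dk[1], L, !cfg$augment)
    y0 <- pick(dk[2], h, !cfg$augment)
    x0 <- pick(dk[3], w, !cfg$augment)
    cand_sd <- stats::sd(kv[z0:(z0 + L - 1L), y0:(y0 + h - 1L),
                            x0:(x0 + w - 1L)])
    if (is.null(best) || cand_sd > best$sd)
      best <- list(z0 = z0, y0 = y0, x0 = x0, sd = cand_sd)
    if (cand_sd >= cfg$min_crop_sd) {
      best <- list(z0 = z0, y0 = y0, x0 = x0, sd = cand_sd)
      break
    }
  }
  z0 <- best$z0; y0 <- best$y0; x0 <- best$x0
  flip <- cfg$augment && stats::runif(1) < 0.5
  thick <- kv[z0:(z0 + L - 1L), y0:(y0 + h - 1L), x0:(x0 + w - 1L),
              drop = FALSE]
  zt0 <- (z0 - 1L) * r + 1L
  thin <- nv[zt0:(zt0 + (L - 1L) * r), y0:(y0 + h - 1L),
             x0:(x0 + w - 1L), drop = FALSE]
  if (flip) {
    thick <- thick[, , rev(seq_len(w)), drop = FALSE]
    thin <- thin[, , rev(seq_len(w)), drop = FALSE]
  }
  list(thick = thick, thin = thin, z0 = z0, y0 = y0, x0 = x0,
       flipped = flip)
}

# ---- learning-rate schedule ----------------------------------------------

sched_init <- function(cfg) {
  list(current_lr = cfg$lr0, consecutive_bad_evals = 0L, drops_done = 0L,
       best_val_psnr = -Inf, best_eval = NA_integer_, n_evals = 0L,
       stopped = FALSE, patience = cfg$patience,
       factor = cfg$lr_drop_factor, max_drops = cfg$max_drops)
}

# one evaluation step of the schedule; a pure function of (state, psnr)
sched_step <- function(s, psnr) {
  s$n_evals <- s$n_evals + 1L
  s$dropped <- FALSE
  if (psnr > s$best_val_psnr) {
    s$best_val_psnr <- psnr
    s$best_eval <- s$n_evals
    s$consecutive_bad_evals <- 0L
  } else {
    s$consecutive_bad_evals <- s$consecutive_bad_evals + 1L
    if (s$consecutive_bad_evals >= s$patience) {
      s$current_lr <- s$current_lr * s$factor
      s$drops_done <- s$drops_done + 1L
      s$consecutive_bad_evals <- 0L
      s$dropped <- TRUE
      if (s$drops_done >= s$max_drops) s$stopped <- TRUE
    }
  }
  s
}

#' Replay the learning-rate schedule over a validation-PSNR history
#'
#' The schedule is a pure function of the evaluation history: the learning
#' rate is multiplied by `lr_drop_factor` whenever `patience` consecutive
#' evaluations fail to exceed the running best, the counter resets after
#' each drop, and training stops after `max_drops` reductions.  Replaying
#' a recorded history therefore reproduces the drop epochs exactly.
#'
#' @param val_psnrs numeric vector of evaluation PSNRs in order.
#' @param cfg a [train_config()].
#' @return A data.frame with one row per evaluation (`eval`, `val_psnr`,
#'   `lr_after`, `dropped`, `stopped`) plus attributes `best_eval` and
#'   `final_lr`.
#' @export
replay_lr_schedule <- function(val_psnrs, cfg = train_config()) {
  s <- sched_init(cfg)
  out <- vector("list", length(val_psnrs))
  for (i in seq_along(val_psnrs)) {
    if (s$stopped) break
    s <- sched_step(s, val_psnrs[i])
    out[[i]] <- data.frame(eval = i, val_psnr = val_psnrs[i],
                           lr_after = s$current_lr, dropped = s$dropped,
                           stopped = s$stopped)
  }
  df <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  attr(df, "best_eval") <- s$best_eval
  attr(df, "final_lr") <- s$current_lr
  df
}

#' Select the checkpoint epoch with the highest validation PSNR
#'
#' Ties break to the earliest epoch.
#'
#' @param state a `train_state` (or any list with `history` containing
#'   `epoch` and `val_psnr` columns).
#' @return The selected epoch.
#' @export
select_checkpoint <- function(state) {
  h <- state$history
  h <- h[!is.na(h$val_psnr), , drop = FALSE]
  if (nrow(h) == 0L) stop("select_checkpoint: no evaluations recorded")
  h$epoch[which.max(h$val_psnr)]
}

# ---- AdamW ----------------------------------------------------------------

adamw_init <- function(flat) {
  list(t = 0L,
       m = lapply(flat, function(p) array(0, dim(p$value) %||% length(p$value))),
       v = lapply(flat, function(p) array(0, dim(p$value) %||% length(p$value))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamw_step <- function(flat, st, lr, cfg) {
  b1 <- cfg$betas[1]; b2 <- cfg$betas[2]
  if (is.finite(cfg$grad_clip)) {
    sq <- sum(vapply(flat, function(p)
      if (is.null(p$grad)) 0 else sum(p$grad^2), 0))
    if (sq > cfg$grad_clip^2) {
      sc <- cfg$grad_clip / sqrt(sq)
      for (p in flat) if (!is.null(p$grad)) p$grad <- p$grad * sc
    }
  }
  st$t <- st$t + 1L
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(flat)) {
    p <- flat[[nm]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    upd <- (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + cfg$eps)
    p$value <- p$value - lr * (upd + cfg$weight_decay * p$value)
    p$grad <- NULL
  }
  st
}

#' Train the synthesis model
#'
#' Each epoch iterates the training samples in a seeded random order with
#' mini-batch 1, taking one AdamW step on the L1 (default) reconstruction
#' loss per sampled cube.  Every `eval_every` epochs the mean validation
#' PSNR is computed on fixed center crops of the validation samples; the
#' learning-rate schedule and stopping rule are driven purely by that
#' evaluation history (see [replay_lr_schedule()]), and the weights with
#' the highest validation PSNR (earliest epoch on ties) are returned.
#'
#' @param model a `dls_model` (modified in place; the returned model
#'   carries the best-evaluation weights).
#' @param train_set,val_set lists of paired samples
#'   (see [make_paired_dataset()]).
#' @param cfg a [train_config()].
#' @param verbose print a line per evaluation.
#' @return List with `model` (best checkpoint) and `state` (a
#'   `train_state`: epoch, current_lr, consecutive_bad_evals, drops_done,
#'   best_val_psnr, best_epoch, and a history data.frame of
#'   (epoch, train_loss, lr, val_psnr)).
#' @export
train_dls <- function(model, train_set, val_set, cfg = train_config(),
                      verbose = FALSE) {
  stopifnot(inherits(model, "dls_model"), length(train_set) >= 1,
            length(val_set) >= 1)
  r <- model$config$r
  flat <- collect_params(model$params)
  opt <- adamw_init(flat)
  sch <- sched_init(cfg)
  hist <- list()
  val_crops <- lapply(val_set, function(s) {
    ccfg <- cfg; ccfg$augment <- FALSE
    if (!is.null(cfg$val_crop)) ccfg$crop <- cfg$val_crop
    sample_training_cube(s, ccfg)
  })
  val_eval <- function() mean(vapply(val_crops, function(vc) {
    psnr(vc$thin, clamp_unit(dls_forward(model, vc$thick)))
  }, 0))
  # the untrained weights are a checkpoint candidate too, so a run whose
  # every evaluation regresses still returns its best-known state
  best_snap <- snapshot_params(model)
  best_epoch <- 0L
  baseline0 <- val_eval()
  best_seen <- baseline0
  with_local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(length(train_set))
      losses <- numeric(length(ord))
      for (k in seq_along(ord)) {
        cube <- sample_training_cube(train_set[[ord[k]]], cfg)
        taped <- ag_with_tape({
          pred <- dls_forward_tensor(model, cube$thick)
          ag_loss(pred, cube$thin, kind = cfg$loss)
        })
        losses[k] <- taped$result$value
        if (!is.finite(losses[k]))
          stop(sprintf(
            "train_dls: non-finite loss %g at epoch %d (lr %g, drops %d)",
            losses[k], epoch, sch$current_lr, sch$drops_done))
        ag_backward(taped)
        opt <- adamw_step(flat, opt, sch$current_lr, cfg)
      }
      val_psnr <- NA_real_
      if (epoch %% cfg$eval_every == 0L) {
        val_psnr <- val_eval()
        sch <- sched_step(sch, val_psnr)
        if (val_psnr > best_seen) {
          best_snap <- snapshot_params(model)
          best_epoch <- epoch
          best_seen <- val_psnr
        }
        if (verbose)
          message(sprintf(
            "epoch %4d  loss %.5f  val PSNR %.2f dB  lr %.2g  drops %d",
            epoch, mean(losses), val_psnr, sch$current_lr, sch$drops_done))
      }
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(losses),
                                  lr = sch$current_lr, val_psnr = val_psnr)
      if (sch$stopped) break
    }
  })
  restore_params(model, best_snap)
  state <- structure(
    list(epoch = length(hist), current_lr = sch$current_lr,
         consecutive_bad_evals = sch$consecutive_bad_evals,
         drops_done = sch$drops_done, best_val_psnr = sch$best_val_psnr,
         best_epoch = best_epoch, baseline_val_psnr = baseline0,
         history = do.call(rbind, hist)),
    class = "train_state")
  list(model = model, state = state)
}
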
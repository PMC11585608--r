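test_that("training crops preserve the coincident-slice alignment", {
  ds <- make_paired_dataset(1, phantom_config(shape_thin = c(41L, 32L, 32L)),
                            seed = 21L)
  cfg <- train_config(crop = c(3L, 16L, 16L), seed = 2L)
  s <- ds[[1]]
  kv <- normalize_hu(s$thick)$values
  nv <- normalize_hu(s$thin)$values
  cubes <- thinCT:::with_local_seed(7L, lapply(1:5, function(i)
    sample_training_cube(s, cfg)))
  cubes2 <- thinCT:::with_local_seed(7L, lapply(1:5, function(i)
    sample_training_cube(s, cfg)))
  for (i in seq_along(cubes)) {
    cb <- cubes[[i]]
    # reproducible under a fixed seed
    expect_identical(cb$z0, cubes2[[i]]$z0)
    expect_identical(cb$flipped, cubes2[[i]]$flipped)
    # thick crop [i, i+L) pairs with thin crop [5 i, 5 i + (L-1) 5 + 1)
    zt0 <- (cb$z0 - 1L) * 5L + 1L
    kk <- kv[cb$z0:(cb$z0 + 2L), cb$y0:(cb$y0 + 15L), cb$x0:(cb$x0 + 15L)]
    nn <- nv[zt0:(zt0 + 10L), cb$y0:(cb$y0 + 15L), cb$x0:(cb$x0 + 15L)]
    if (cb$flipped) {
      kk <- kk[, , 16:1]; nn <- nn[, , 16:1]
    }
    expect_equal(cb$thick, kk)
    expect_equal(cb$thin, nn)
  }
})

test_that("flipped crops remain a valid degradation pair away from ends", {
  ds <- make_paired_dataset(1, phantom_config(shape_thin = c(41L, 32L, 32L)),
                            seed = 22L)
  cfg <- train_config(crop = c(3L, 20L, 20L), seed = 3L)
  cb <- thinCT:::with_local_seed(12L, {
    repeat {
      x <- sample_training_cube(ds[[1]], cfg)
      if (x$flipped && x$z0 > 1L && (x$z0 + 2L) < 9L) break
    }
    x
  })
  thin_v <- ct_volume(cb$thin, space = "unit")
  redegraded <- degrade_to_thick(thin_v, 5L)$values
  # interior thick slices of the crop equal the re-degraded thin crop
  expect_equal(redegraded[2, , ], cb$thick[2, , ], tolerance = 1e-12)
})

test_that("the LR schedule reproduces the stated drop/stop/best rules", {
  cfg <- train_config(lr0 = 3e-4)
  # three consecutive non-improving evals trigger exactly one drop
  df <- replay_lr_schedule(c(10.0, 9.9, 9.8, 9.7), cfg)
  expect_identical(which(df$dropped), 4L)
  expect_equal(df$lr_after[4], 3e-5)
  expect_identical(attr(df, "best_eval"), 1L)
  # monotone improvement: no drop, best is the last evaluation
  df <- replay_lr_schedule(c(10, 11, 12), cfg)
  expect_false(any(df$dropped))
  expect_identical(attr(df, "best_eval"), 3L)
  expect_equal(attr(df, "final_lr"), 3e-4)
  # after three drops the LR is lr0/1000 and training has stopped
  hist <- c(20, rep(19, 9))
  df <- replay_lr_schedule(hist, cfg)
  expect_identical(sum(df$dropped), 3L)
  expect_equal(attr(df, "final_lr"), 3e-4 * 1e-3)
  expect_true(df$stopped[nrow(df)])
  expect_identical(nrow(df), 10L)  # evaluations after the stop are ignored
  # counter resets after a drop: improvements in between delay the next
  df <- replay_lr_schedule(c(10, 9, 9, 9, 11, 9, 9, 9, 9), cfg)
  expect_identical(which(df$dropped), c(4L, 8L))
})

test_that("checkpoint selection takes the highest PSNR, earliest on ties", {
  st <- list(history = data.frame(epoch = c(5L, 10L, 15L),
                                  val_psnr = c(20, 25, 24)))
  expect_identical(select_checkpoint(st), 10L)
  st <- list(history = data.frame(epoch = c(5L, 10L),
                                  val_psnr = c(20, 20)))
  expect_identical(select_checkpoint(st), 5L)
  st <- list(history = data.frame(epoch = 5L, val_psnr = 17))
  expect_identical(select_checkpoint(st), 5L)
  expect_error(select_checkpoint(list(history = data.frame(
    epoch = integer(), val_psnr = numeric()))), "no evaluations")
})

test_that("training learns: later-epoch loss is below first-epoch loss", {
  ds <- make_paired_dataset(2, phantom_config(shape_thin = c(16L, 16L, 16L),
                                              noise_sd = 10),
                            seed = 31L)
  # without the residual skip the loss starts far from the floor, so the
  # descent is unambiguous
  m <- new_dls_model(dls_config("tiny", L = 2L, global_residual = FALSE),
                     seed = 2L)
  cfg <- train_config(lr0 = 3e-3, loss = "l2", crop = c(2L, 16L, 16L),
                      max_epochs = 20L, eval_every = 10L, grad_clip = 1,
                      seed = 4L)
  fit <- train_dls(m, ds, ds, cfg)
  h <- fit$state$history
  expect_lt(h$train_loss[20], h$train_loss[1])
  expect_s3_class(fit$state, "train_state")
  expect_true(all(diff(h$epoch) == 1))
})
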
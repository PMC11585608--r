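tiny_cfg <- function(L = 2L, ...) {
  dls_config("tiny", L = L, embed_dim = 8L, n_heads = 2L, enc_depth = 1L,
             dec_depth = 1L, window_3d = c(2L, 2L, 2L),
             window_2d = c(2L, 2L), ...)
}

test_that("forward obeys the (L-1)*r+1 output-size law", {
  for (L in c(2L, 3L, 5L, 8L)) {
    m <- new_dls_model(tiny_cfg(L = L), seed = 1L)
    cube <- array(0.5, c(L, 8, 8))
    out <- dls_forward(m, cube)
    expect_identical(dim(out), c((L - 1L) * 5L + 1L, 8L, 8L))
  }
  # r other than 5 follows the same law
  m <- new_dls_model(tiny_cfg(L = 3L, r = 3L), seed = 1L)
  expect_identical(dim(dls_forward(m, array(0.2, c(3, 8, 8))))[1], 7L)
  expect_error(dls_forward(m, array(0.2, c(4, 8, 8))), "config L")
})

test_that("mask token add expands L encoder slices to (L-1)*r+1 positions", {
  for (L in c(2L, 8L)) {
    lat <- thinCT:::ag_tensor(array(rnorm(L * 4 * 4 * 8), c(L, 4, 4, 8)))
    p <- list(mask_token = thinCT:::ag_tensor(rnorm(8), TRUE),
              mask_pe = thinCT:::ag_tensor(matrix(0, 5, 8), TRUE))
    out <- thinCT:::mask_token_add(lat, p, 5L)
    expect_identical(dim(out$value)[1], (L - 1L) * 5L + 1L)
    # with zero phase embedding, coincident positions carry the encoder
    # features exactly and masked positions the shared token
    coin <- seq(1L, (L - 1L) * 5L + 1L, by = 5L)
    expect_equal(out$value[coin, , , ], lat$value[, , , ])
    expect_equal(out$value[2, 1, 1, ], p$mask_token$value)
    expect_equal(out$value[2, , , ], out$value[4, , , ])
  }
})

test_that("zeroed residual branches make every block an identity", {
  m <- zero_residual_init(new_dls_model(tiny_cfg(L = 2L), seed = 5L))
  set.seed(8)
  x <- thinCT:::ag_tensor(array(rnorm(2 * 8 * 8 * 8), c(2, 8, 8, 8)))
  cfg <- m$config
  for (shifted in c(FALSE, TRUE)) {
    y <- thinCT:::stl_forward(x, m$params$enc[[1]]$stls[[1]], cfg, 3L,
                              shifted)
    expect_equal(y$value, x$value, tolerance = 1e-12)
  }
  y <- thinCT:::cth_block_forward(x, m$params$enc[[1]], cfg, 3L)
  expect_equal(y$value, x$value, tolerance = 1e-12)
  xd <- thinCT:::ag_tensor(array(rnorm(6 * 8 * 8 * 8), c(6, 8, 8, 8)))
  y <- thinCT:::tcth_block_forward(xd, m$params$dec[[1]], cfg)
  expect_equal(y$value, xd$value, tolerance = 1e-12)
})

test_that("STL preserves shape and is shift-invariant on constant input", {
  m <- new_dls_model(tiny_cfg(L = 2L), seed = 9L)
  cfg <- m$config
  xc <- thinCT:::ag_tensor(array(0.37, c(4, 8, 8, 8)))
  y0 <- thinCT:::stl_forward(xc, m$params$enc[[1]]$stls[[1]], cfg, 3L, FALSE)
  y1 <- thinCT:::stl_forward(xc, m$params$enc[[1]]$stls[[1]], cfg, 3L, TRUE)
  expect_identical(dim(y0$value), dim(xc$value))
  expect_equal(y0$value, y1$value, tolerance = 1e-10)
  set.seed(10)
  xr <- thinCT:::ag_tensor(array(rnorm(4 * 8 * 8 * 8), c(4, 8, 8, 8)))
  yr <- thinCT:::stl_forward(xr, m$params$enc[[1]]$stls[[1]], cfg, 3L, TRUE)
  expect_identical(dim(yr$value), dim(xr$value))
  expect_error(
    thinCT:::stl_forward(thinCT:::ag_tensor(array(0, c(2, 4, 4, 5))),
                         m$params$enc[[1]]$stls[[1]], cfg, 3L, FALSE),
    "channel")
})

test_that("view permutations are involutions and branches are symmetric", {
  set.seed(11)
  x <- array(rnorm(6 * 4 * 5 * 3), c(6, 4, 5, 3))
  pa <- aperm(aperm(x, c(2, 1, 3, 4)), c(2, 1, 3, 4))
  expect_identical(pa, x)
  ps <- aperm(aperm(x, c(3, 1, 2, 4)), c(2, 3, 1, 4))
  expect_identical(ps, x)
  # swapping y and x of the input swaps the two branch contributions
  m <- new_dls_model(tiny_cfg(L = 2L), seed = 12L)
  p <- m$params$dec[[1]]
  # tie the two branches to identical weights
  wa <- thinCT:::collect_params(p$coronal)
  wb <- thinCT:::collect_params(p$sagittal)
  for (nm in names(wa)) wb[[nm]]$value <- wa[[nm]]$value
  xs <- thinCT:::ag_tensor(array(rnorm(6 * 8 * 8 * 8), c(6, 8, 8, 8)))
  y <- thinCT:::tcth_block_forward(xs, p, m$config)$value
  xswap <- thinCT:::ag_tensor(aperm(xs$value, c(1, 3, 2, 4)))
  yswap <- thinCT:::tcth_block_forward(xswap, p, m$config)$value
  expect_equal(aperm(yswap, c(1, 3, 2, 4)), y, tolerance = 1e-10)
})

test_that("forward is deterministic and finite", {
  m <- new_dls_model(tiny_cfg(L = 4L), seed = 13L)
  set.seed(14)
  cube <- array(runif(4 * 12 * 12), c(4, 12, 12))  # needs padding in-plane
  o1 <- dls_forward(m, cube)
  o2 <- dls_forward(m, cube)
  expect_identical(o1, o2)
  expect_true(all(is.finite(o1)))
})

test_that("checkpoints round-trip config and weights", {
  m <- new_dls_model(tiny_cfg(L = 3L), seed = 15L)
  path <- file.path(tempdir(), "model.rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$config$L, 3L)
  cube <- array(0.3, c(3, 8, 8))
  expect_identical(dls_forward(m, cube), dls_forward(m2, cube))
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")), "no such")
})

test_that("a tiny model can overfit one synthetic pair to >= 30 dB", {
  ds <- make_paired_dataset(1, phantom_config(shape_thin = c(16L, 16L, 16L),
                                              noise_sd = 5),
                            seed = 99L)
  m <- new_dls_model(dls_config("tiny", L = 2L), seed = 1L)
  cfg <- train_config(lr0 = 3e-3, loss = "l2", crop = c(2L, 16L, 16L),
                      max_epochs = 80L, eval_every = 10L, augment = FALSE,
                      grad_clip = 1, seed = 1L)
  fit <- train_dls(m, ds, ds, cfg)
  # validation here is the fixed training cube itself (gradient-path sanity)
  expect_gte(fit$state$best_val_psnr, 30)
})
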
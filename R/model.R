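#' Model configuration for the thin-slice synthesis network
#'
#' The network is an asymmetric encoder-decoder.  The encoder applies 3-D
#' convolutional-transformer hybrid (CTH) blocks -- four shifted-window
#' attention layers (STLs) followed by a kernel-3 convolution -- to the `L`
#' visible thick slices.  The Mask Token Add module expands the latent
#' representation to `(L - 1) * r + 1` axial positions, placing a learnable
#' mask token (plus a phase embedding indexed by `z mod r`) at the missing
#' thin-slice positions.  The decoder applies through-plane CTH (T-CTH)
#' blocks whose two branches run 2-D CTH blocks over coronal and sagittal
#' views, and a final per-voxel linear projection emits intensities.
#'
#' Following the architecture's design, shifted windows carry no
#' cross-sub-window attention mask by default (`use_attention_mask =
#' FALSE`), so attention within a shifted window spans the wrapped
#' content.
#'
#' With `global_residual = TRUE` (default) the network output is a learned
#' correction added to a Catmull-Rom axial interpolation of the input, the
#' residual-learning formulation standard in super-resolution networks;
#' the final projection is then zero-initialized so an untrained model
#' reproduces the interpolation exactly and optimization only has to learn
#' the correction.  Set it to `FALSE` for the pure masked-recovery
#' pipeline.
#'
#' Two presets are provided: `"tiny"` (embed 32, depths 2/2, 4 heads,
#' windows (2,4,4)/(4,4)) for desk-scale runs, and `"full"` (embed 96,
#' depths 4/4, 6 heads, windows (2,8,8)/(8,8)) as a plausible full-scale
#' default; widths and depths at full scale are implementation choices.
#'
#' @param preset `"tiny"` or `"full"`.
#' @param r integer upsampling factor (>= 2).
#' @param L input slice count (>= 2).
#' @param ... overrides for any config field (`embed_dim`, `enc_depth`,
#'   `dec_depth`, `stls_per_block`, `window_3d`, `window_2d`, `n_heads`,
#'   `mlp_ratio`, `use_attention_mask`, `loss`, `global_residual`).
#' @return A `dls_config` list.
#' @export
dls_config <- function(preset = c("tiny", "full"), r = 5L, L = 8L, ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    tiny = list(embed_dim = 32L, enc_depth = 2L, dec_depth = 2L,
                stls_per_block = 4L, window_3d = c(2L, 4L, 4L),
                window_2d = c(4L, 4L), n_heads = 4L, mlp_ratio = 2),
    full = list(embed_dim = 96L, enc_depth = 4L, dec_depth = 4L,
                 stls_per_block = 4L, window_3d = c(2L, 8L, 8L),
                 window_2d = c(8L, 8L), n_heads = 6L, mlp_ratio = 4))
  cfg$preset <- preset
  cfg$r <- as.integer(r); cfg$L <- as.integer(L)
  cfg$use_attention_mask <- FALSE
  cfg$loss <- "l1"
  cfg$global_residual <- TRUE
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  if (cfg$r < 2L) stop("r must be >= 2")
  if (cfg$L < 2L) stop("L must be >= 2")
  if (cfg$embed_dim %% cfg$n_heads != 0L)
    stop("embed_dim must be divisible by n_heads")
  if (any(c(cfg$window_3d, cfg$window_2d) < 2L))
    stop("window sizes must be >= 2")
  if (cfg$stls_per_block %% 2L != 0L)
    stop("stls_per_block must be even (W-MSA/SW-MSA pairing)")
  structure(cfg, class = "dls_config")
}

# relative-position-bias index matrix for a window of dims `win`
rpb_index <- function(win) {
  coords <- as.matrix(do.call(expand.grid, lapply(win, seq_len)))
  w <- nrow(coords)
  idx <- matrix(0L, w, w)
  stride <- cumprod(c(1, 2 * win - 1))[seq_along(win)]
  for (k in seq_along(win)) {
    rel <- outer(coords[, k], coords[, k], "-") + win[k] - 1L
    idx <- idx + rel * stride[k]
  }
  idx + 1L
}

rnorm_arr <- function(dims, sd = 0.02) array(stats::rnorm(prod(dims), 0, sd), dims)

init_stl <- function(C, heads, win) {
  n_rel <- prod(2L * win - 1L)
  list(ln1_g = ag_tensor(rep(1, C), TRUE), ln1_b = ag_tensor(rep(0, C), TRUE),
       Wq = ag_tensor(rnorm_arr(c(C, C)), TRUE), bq = ag_tensor(rep(0, C), TRUE),
       Wk = ag_tensor(rnorm_arr(c(C, C)), TRUE), bk = ag_tensor(rep(0, C), TRUE),
       Wv = ag_tensor(rnorm_arr(c(C, C)), TRUE), bv = ag_tensor(rep(0, C), TRUE),
       Wo = ag_tensor(rnorm_arr(c(C, C)), TRUE), bo = ag_tensor(rep(0, C), TRUE),
       rpb = ag_tensor(matrix(0, n_rel, heads), TRUE),
       ln2_g = ag_tensor(rep(1, C), TRUE), ln2_b = ag_tensor(rep(0, C), TRUE),
       W1 = ag_tensor(rnorm_arr(c(C, round(C * 2))), TRUE),
       b1 = ag_tensor(rep(0, round(C * 2)), TRUE),
       W2 = ag_tensor(rnorm_arr(c(round(C * 2), C)), TRUE),
       b2 = ag_tensor(rep(0, C), TRUE))
}

init_cth <- function(cfg, dims) {
  C <- cfg$embed_dim
  win <- if (dims == 3L) cfg$window_3d else cfg$window_2d
  n_off <- 3L^length(win)
  mlp_hidden <- round(C * cfg$mlp_ratio)
  stls <- lapply(seq_len(cfg$stls_per_block), function(i) {
    p <- init_stl(C, cfg$n_heads, win)
    p$W1 <- ag_tensor(rnorm_arr(c(C, mlp_hidden)), TRUE)
    p$b1 <- ag_tensor(rep(0, mlp_hidden), TRUE)
    p$W2 <- ag_tensor(rnorm_arr(c(mlp_hidden, C)), TRUE)
    p$b2 <- ag_tensor(rep(0, C), TRUE)
    p
  })
  list(stls = stls,
       conv_W = ag_tensor(rnorm_arr(c(C, C, n_off), sd = 0.02), TRUE),
       conv_b = ag_tensor(rep(0, C), TRUE))
}

#' Create a thin-slice synthesis model with freshly initialized weights
#'
#' Weight matrices are drawn from N(0, 0.02^2); layer-norm gains start at
#' 1, biases, relative-position-bias tables and the axial phase embedding
#' at 0.  Initialization, and nothing else in the forward pass, consumes
#' randomness, so a model is fully reproducible from `(config, seed)`.
#'
#' @param cfg a [dls_config()].
#' @param seed integer seed for weight initialization.
#' @return A `dls_model` (list with `config` and `params`).
#' @export
new_dls_model <- function(cfg = dls_config(), seed = 1L) {
  stopifnot(inherits(cfg, "dls_config"))
  with_local_seed(seed, {
    C <- cfg$embed_dim
    params <- list(
      # intensity-broadcast initialization: channels start as jittered
      # copies of the input intensity so the input->projection path
      # carries an O(1) signal immediately; the jitter on both weight and
      # bias keeps the across-channel variance seen by the first layer
      # norm bounded away from zero for any input value
      embed_W = ag_tensor(matrix(stats::rnorm(C, 1, 0.1), 1, C), TRUE),
      embed_b = ag_tensor(stats::rnorm(C, 0, 0.1), TRUE),
      enc = lapply(seq_len(cfg$enc_depth), function(i) init_cth(cfg, 3L)),
      mask_token = ag_tensor(stats::rnorm(C, 0, 0.02), TRUE),
      mask_pe = ag_tensor(matrix(0, cfg$r, C), TRUE),
      dec = lapply(seq_len(cfg$dec_depth), function(i)
        list(coronal = init_cth(cfg, 2L), sagittal = init_cth(cfg, 2L))),
      # with the global residual skip the projection starts at zero, so
      # the untrained network reproduces the axial interpolation exactly
      # and training learns a correction on top of it
      proj_W = ag_tensor(if (isTRUE(cfg$global_residual)) matrix(0, C, 1)
                         else rnorm_arr(c(C, 1)), TRUE),
      proj_b = ag_tensor(0, TRUE))
    structure(list(config = cfg, params = params), class = "dls_model")
  })
}

#' @export
print.dls_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<dls_model> preset '%s': r=%d, L=%d, embed %d, enc %d x 3D-CTH, dec %d x T-CTH, %d heads\n",
    cfg$preset, cfg$r, cfg$L, cfg$embed_dim, cfg$enc_depth, cfg$dec_depth,
    cfg$n_heads))
  n <- sum(vapply(collect_params(x$params), function(p) length(p$value), 0))
  cat(sprintf("  %d parameters\n", n))
  invisible(x)
}

# flatten the nested parameter list into a named list of ag_tensors
collect_params <- function(p, prefix = "") {
  if (inherits(p, "ag_tensor"))
    return(stats::setNames(list(p), prefix))
  out <- list()
  nms <- names(p)
  for (i in seq_along(p)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    out <- c(out, collect_params(p[[i]], paste0(prefix, "/", nm)))
  }
  out
}

# ---- forward passes -------------------------------------------------------

# partition a (Z,Y,X,C) tensor into non-overlapping windows -> (w, nw, C);
# fused reshape+aperm chains realized as one cached index permutation
win_partition3 <- function(x, win) {
  d <- dim(x$value)
  nb <- d[1:3] %/% win
  p <- cached_perm(paste("p3", paste(d, collapse = ","),
                         paste(win, collapse = ",")), function()
    build_perm(c(win[1], nb[1], win[2], nb[2], win[3], nb[3], d[4]),
               c(1, 3, 5, 2, 4, 6, 7),
               c(prod(win), prod(nb), d[4]), gdim = d))
  ag_permute(x, p)
}

win_merge3 <- function(x, win, sp, C) {
  nb <- sp %/% win
  p <- cached_perm(paste("m3", paste(sp, collapse = ","),
                         paste(win, collapse = ","), C), function()
    build_perm(c(win, nb, C), c(1, 4, 2, 5, 3, 6, 7), c(sp, C),
               gdim = c(prod(win), prod(nb), C)))
  ag_permute(x, p)
}

# 2-D variant: axis 1 is a batch of planes, windows tile axes 2:3
win_partition2 <- function(x, win) {
  d <- dim(x$value)
  nb <- d[2:3] %/% win
  p <- cached_perm(paste("p2", paste(d, collapse = ","),
                         paste(win, collapse = ",")), function()
    build_perm(c(d[1], win[1], nb[1], win[2], nb[2], d[4]),
               c(2, 4, 1, 3, 5, 6),
               c(prod(win), d[1] * prod(nb), d[4]), gdim = d))
  ag_permute(x, p)
}

win_merge2 <- function(x, win, sp, C) {
  nb <- sp[2:3] %/% win
  p <- cached_perm(paste("m2", paste(sp, collapse = ","),
                         paste(win, collapse = ","), C), function()
    build_perm(c(win[1], win[2], sp[1], nb[1], nb[2], C),
               c(3, 1, 4, 2, 5, 6), c(sp, C),
               gdim = c(prod(win), sp[1] * prod(nb), C)))
  ag_permute(x, p)
}

window_attention <- function(xw, p, heads, idx) {
  d <- dim(xw$value)
  w <- d[1]; nw <- d[2]; C <- d[3]
  hd <- C %/% heads
  ps <- cached_perm(paste("hs", w, nw, C, heads), function()
    build_perm(c(w, nw, hd, heads), c(1, 3, 2, 4), c(w, hd, nw * heads),
               gdim = c(w, nw, C)))
  pm <- cached_perm(paste("hm", w, nw, C, heads), function()
    build_perm(c(w, hd, nw, heads), c(1, 3, 2, 4), c(w, nw, C),
               gdim = c(w, hd, nw * heads)))
  q <- ag_permute(ag_linear(xw, p$Wq, p$bq), ps)
  k <- ag_permute(ag_linear(xw, p$Wk, p$bk), ps)
  v <- ag_permute(ag_linear(xw, p$Wv, p$bv), ps)
  att <- ag_bmm(ag_scale(q, 1 / sqrt(hd)), k, tb = TRUE)
  att <- ag_rpb(att, p$rpb, idx, nw, heads)
  mask <- attr(xw, "attn_mask")
  if (!is.null(mask))
    att <- ag_add_const(att, mask[, , rep(seq_len(nw), heads), drop = FALSE])
  att <- ag_softmax2(att)
  o <- ag_permute(ag_bmm(att, v), pm)
  ag_linear(o, p$Wo, p$bo)
}

#' Shifted-window transformer layer (STL)
#'
#' Pre-norm residual layer: `x + WindowAttention(LN(x))` followed by
#' `+ MLP(LN(.))`.  With `shifted = TRUE` the feature grid is cyclically
#' shifted by half a window before partitioning and shifted back after;
#' when `cfg$use_attention_mask` is `FALSE` (the default) attention within
#' each shifted window is computed without the cross-sub-window mask.
#'
#' @param x an `ag_tensor` feature cube `(Z, Y, X, C)` (for `dims = 2`,
#'   axis 1 is a batch of planes and windows tile axes 2-3).
#' @param p STL parameter list.
#' @param cfg a [dls_config()].
#' @param dims 2 or 3.
#' @param shifted logical.
#' @return An `ag_tensor` of the same shape.
#' @keywords internal
stl_forward <- function(x, p, cfg, dims, shifted) {
  d <- dim(x$value)
  if (d[4] != cfg$embed_dim)
    stop(sprintf("stl_forward: channel count %d != embed_dim %d",
                 d[4], cfg$embed_dim))
  win <- if (dims == 3L) cfg$window_3d else cfg$window_2d
  sp_axes <- if (dims == 3L) 1:3 else 2:3
  padded <- d[1:3]
  padded[sp_axes] <- ((d[sp_axes] + win - 1L) %/% win) * win
  shift <- if (shifted) win %/% 2L else integer(length(win)) * 0L
  full_shift <- c(0L, 0L, 0L); full_shift[sp_axes] <- shift

  h <- ag_layernorm(x, p$ln1_g, p$ln1_b)
  h <- ag_pad3(h, padded)
  if (shifted) h <- ag_roll(h, -full_shift)
  xw <- if (dims == 3L) win_partition3(h, win) else win_partition2(h, win)
  if (shifted && isTRUE(cfg$use_attention_mask))
    attr(xw, "attn_mask") <- swin_mask(padded, win, shift, dims)
  idx <- rpb_index(win)
  a <- window_attention(xw, p, cfg$n_heads, idx)
  a <- if (dims == 3L) win_merge3(a, win, padded, d[4])
       else win_merge2(a, win, padded, d[4])
  if (shifted) a <- ag_roll(a, full_shift)
  a <- ag_crop3(a, d[1:3])
  x <- ag_add(x, a)

  h <- ag_layernorm(x, p$ln2_g, p$ln2_b)
  h <- ag_linear(h, p$W1, p$b1)
  h <- ag_gelu(h)
  h <- ag_linear(h, p$W2, p$b2)
  ag_add(x, h)
}

# per-window mask (w, w, nw) marking cross-sub-window pairs with -100
swin_mask <- function(sp, win, shift, dims) {
  band_id <- function(S, w, s) {
    id <- integer(S)
    if (s > 0L && S > w) {
      id[(S - w + 1L):S] <- 1L
      id[(S - s + 1L):S] <- 2L
    }
    id
  }
  if (dims == 3L) {
    ids <- array(0, sp)
    ids <- ids + band_id(sp[1], win[1], shift[1]) * 100
    ids <- ids + rep(rep(band_id(sp[2], win[2], shift[2]) * 10,
                         each = sp[1]), sp[3])
    ids <- ids + rep(band_id(sp[3], win[3], shift[3]), each = sp[1] * sp[2])
    grid <- roll_arr4(array(ids, c(sp, 1)), -c(shift, 0L))
    part <- win_partition3(ag_tensor(grid), win)$value
  } else {
    ids <- array(0, sp)
    ids <- ids + rep(rep(band_id(sp[2], win[1], shift[1]) * 10,
                         each = sp[1]), sp[3])
    ids <- ids + rep(band_id(sp[3], win[2], shift[2]), each = sp[1] * sp[2])
    grid <- roll_arr4(array(ids, c(sp, 1)), -c(0L, shift, 0L))
    part <- win_partition2(ag_tensor(grid), win)$value
  }
  w <- dim(part)[1]; nw <- dim(part)[2]
  m <- array(0, c(w, w, nw))
  for (k in seq_len(nw))
    m[, , k] <- ifelse(outer(part[, k, 1], part[, k, 1], "!="), -100, 0)
  m
}

#' Convolutional-transformer hybrid (CTH) block
#'
#' `stls_per_block` STLs alternating regular and shifted windows, then a
#' channel-preserving kernel-3 convolution whose output is added residually
#' to the block input: `out = x + Conv(STL_chain(x))`.
#'
#' @inheritParams stl_forward
#' @param p CTH block parameter list (`stls`, `conv_W`, `conv_b`).
#' @return An `ag_tensor` of the same shape.
#' @keywords internal
cth_block_forward <- function(x, p, cfg, dims) {
  h <- x
  for (s in seq_along(p$stls))
    h <- stl_forward(h, p$stls[[s]], cfg, dims, shifted = (s %% 2L == 0L))
  h <- ag_conv(h, p$conv_W, p$conv_b, axes = if (dims == 3L) 1:3 else 2:3)
  ag_add(x, h)
}

#' Through-plane CTH (T-CTH) block
#'
#' Two parallel branches permute the feature cube so that rows (coronal
#' view) or columns (sagittal view) become the plane index, run a 2-D CTH
#' block per plane, and permute back; the branch residuals are fused by
#' element-wise sum: `out = x + (A(x) - x) + (B(x) - x)`.
#'
#' @inheritParams stl_forward
#' @param p list with `coronal` and `sagittal` CTH parameter lists.
#' @return An `ag_tensor` of the same shape.
#' @keywords internal
tcth_block_forward <- function(x, p, cfg) {
  xa <- ag_aperm(x, c(2, 1, 3, 4))               # (Y, Z, X, C)
  ya <- cth_block_forward(xa, p$coronal, cfg, dims = 2L)
  da <- ag_aperm(ag_sub(ya, xa), c(2, 1, 3, 4))
  xb <- ag_aperm(x, c(3, 1, 2, 4))               # (X, Z, Y, C)
  yb <- cth_block_forward(xb, p$sagittal, cfg, dims = 2L)
  db <- ag_aperm(ag_sub(yb, xb), c(2, 3, 1, 4))
  ag_add(ag_add(x, da), db)
}

#' Mask Token Add module
#'
#' Expands encoder features over `L` visible slices to `(L - 1) * r + 1`
#' axial positions: position `r*i` carries the feature of visible slice
#' `i`, every other position carries the shared learnable mask token, and
#' a learnable phase embedding indexed by `z mod r` is added everywhere.
#'
#' @param latent an `ag_tensor` `(L, Y, X, C)`.
#' @param params model parameter list (uses `mask_token`, `mask_pe`).
#' @param r upsampling factor.
#' @return An `ag_tensor` `((L-1)*r+1, Y, X, C)`.
#' @keywords internal
mask_token_add <- function(latent, params, r) {
  ag_mask_scatter(latent, params$mask_token, params$mask_pe, r)
}

# full forward pass on a normalized (L, H, W) array; returns an ag_tensor
dls_forward_tensor <- function(model, cube) {
  cfg <- model$config; p <- model$params
  d <- dim(cube)
  if (d[1] != cfg$L)
    stop(sprintf("forward: input has %d slices but config L = %d",
                 d[1], cfg$L))
  x <- ag_tensor(array(cube, c(d, 1)))
  x <- ag_linear(x, p$embed_W, p$embed_b)
  for (blk in p$enc) x <- cth_block_forward(x, blk, cfg, dims = 3L)
  x <- mask_token_add(x, p, cfg$r)
  for (blk in p$dec) x <- tcth_block_forward(x, blk, cfg)
  y <- ag_linear(x, p$proj_W, p$proj_b)
  y <- ag_reshape(y, c((d[1] - 1L) * cfg$r + 1L, d[2], d[3]))
  if (isTRUE(cfg$global_residual)) {
    base <- bicubic_z_matrix(d[1], cfg$r) %*% matrix(cube, d[1])
    y <- ag_add_const(y, array(base, dim(y$value)))
  }
  y
}

#' Run the synthesis network on one thick-slice cube
#'
#' Maps a normalized `(L, H, W)` cube of thick slices to the
#' `((L-1)*r+1, H, W)` cube of synthetic thin slices.  Deterministic given
#' the weights; no gradient bookkeeping is performed.
#'
#' @param model a `dls_model`.
#' @param cube numeric `(L, H, W)` array with values in `[0, 1]`.
#' @return Numeric `((L-1)*r+1, H, W)` array.
#' @export
dls_forward <- function(model, cube) {
  stopifnot(inherits(model, "dls_model"))
  dls_forward_tensor(model, cube)$value
}

#' Zero all residual-path output weights of a model
#'
#' Sets attention output projections, MLP second layers, convolution
#' kernels and their biases to zero, making every STL, CTH and T-CTH block
#' an exact identity.  Diagnostic helper for verifying the residual
#' topology of the network.
#'
#' @param model a `dls_model`.
#' @return The modified model.
#' @export
zero_residual_init <- function(model) {
  zero_cth <- function(blk) {
    for (s in seq_along(blk$stls)) {
      blk$stls[[s]]$Wo$value[] <- 0
      blk$stls[[s]]$bo$value[] <- 0
      blk$stls[[s]]$W2$value[] <- 0
      blk$stls[[s]]$b2$value[] <- 0
    }
    blk$conv_W$value[] <- 0
    blk$conv_b$value[] <- 0
  }
  for (blk in model$params$enc) zero_cth(blk)
  for (blk in model$params$dec) { zero_cth(blk$coronal); zero_cth(blk$sagittal) }
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS file holding the configuration and all
#' weight arrays.
#'
#' @param model a `dls_model`.
#' @param path destination file.
#' @return `path` invisibly (`save_checkpoint`); a `dls_model`
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dls_model"))
  flat <- collect_params(model$params)
  saveRDS(list(config = unclass(model$config),
               weights = lapply(flat, function(p) p$value)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop(sprintf("load_checkpoint: no such file '%s'", path))
  ck <- readRDS(path)
  cfg <- structure(ck$config, class = "dls_config")
  model <- new_dls_model(cfg, seed = 0L)
  flat <- collect_params(model$params)
  if (!setequal(names(flat), names(ck$weights)))
    stop("load_checkpoint: weight names do not match configuration")
  for (nm in names(flat)) flat[[nm]]$value <- ck$weights[[nm]]
  model
}

# deep copy of the parameter values (for checkpoint-best bookkeeping)
snapshot_params <- function(model) {
  lapply(collect_params(model$params), function(p) p$value)
}

restore_params <- function(model, snap) {
  flat <- collect_params(model$params)
  for (nm in names(flat)) flat[[nm]]$value <- snap[[nm]]
  model
}
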
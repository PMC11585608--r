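#' Plan sliding windows for whole-volume synthesis
#'
#' Axial windows of `L` thick slices advance with stride `L - overlap`
#' (the protocol uses overlap 1, so consecutive windows share one input
#' slice); if the last stride overshoots, a final window anchored at
#' `D - L` is appended so every slice is covered.  In-plane tiles advance
#' with zero overlap at stride `tile`, with a final tile anchored to the
#' far edge when the extent is not a multiple.  Starts are 0-based.
#'
#' @param D thick slice count.
#' @param L window length in thick slices.
#' @param overlap axial overlap in thick slices.
#' @param H,W in-plane extents.
#' @param tile in-plane tile size `(th, tw)`.
#' @return A `window_plan` list with `z_starts`, `y_starts`, `x_starts`,
#'   `L`, `tile` (all starts 0-based).
#' @export
plan_windows <- function(D, L = 8L, overlap = 1L, H = 256L, W = 256L,
                         tile = c(256L, 256L)) {
  D <- as.integer(D); L <- as.integer(L)
  if (D < L)
    stop(sprintf(
      "plan_windows: volume has %d slices but the model needs %d", D, L))
  if (overlap < 0L || overlap >= L)
    stop("plan_windows: need 0 <= overlap < L")
  stride <- L - as.integer(overlap)
  z <- seq.int(0L, D - L, by = stride)
  if (z[length(z)] != D - L) z <- c(z, D - L)
  tile_starts <- function(S, t) {
    if (S <= t) return(0L)
    s <- seq.int(0L, S - t, by = t)
    if (s[length(s)] != S - t) s <- c(s, S - t)
    as.integer(s)
  }
  th <- as.integer(min(tile[1], H)); tw <- as.integer(min(tile[2], W))
  structure(list(z_starts = as.integer(z), L = L,
                 y_starts = tile_starts(as.integer(H), th),
                 x_starts = tile_starts(as.integer(W), tw),
                 tile = c(th, tw), overlap = as.integer(overlap)),
            class = "window_plan")
}

#' Synthesize a full thin-slice volume by sliding-window inference
#'
#' The thick volume is normalized, tiled according to [plan_windows()]
#' (axial overlap 1, in-plane overlap 0 by default), each window is run
#' through the model, predictions are anchored at thin index `r*start`,
#' and multiple predictions for the same thin coordinate are averaged.
#' The result is clamped to the normalized range, mapped back to HU, and
#' returned with `dz_out = dz_in / r`.
#'
#' @param model a `dls_model`, or (for stubs and baselines) a function
#'   mapping a normalized `(L, h, w)` array to a `((L-1)r+1, h, w)` array.
#' @param thick a `ct_volume` in HU space.
#' @param overlap axial overlap in thick slices.
#' @param tile in-plane tile size.
#' @param L,r window length and upsampling factor; taken from the model
#'   config when `model` is a `dls_model`.
#' @return A `ct_volume` with `(D - 1) * r + 1` slices in HU space.
#' @export
synthesize_thin <- function(model, thick, overlap = 1L,
                            tile = c(256L, 256L), L = NULL, r = NULL) {
  stopifnot(is_ct_volume(thick))
  if (inherits(model, "dls_model")) {
    L <- model$config$L; r <- model$config$r
    fwd <- function(cube) dls_forward(model, cube)
  } else if (is.function(model)) {
    if (is.null(L) || is.null(r))
      stop("synthesize_thin: L and r must be given for a function model")
    fwd <- model
  } else stop("synthesize_thin: model must be a dls_model or a function")
  d <- dim(thick$values)
  plan <- plan_windows(d[1], L, overlap, d[2], d[3], tile)
  nv <- normalize_hu(thick)$values
  Dt <- (d[1] - 1L) * r + 1L
  Lt <- (L - 1L) * r + 1L
  acc <- array(0, c(Dt, d[2], d[3]))
  cnt <- array(0, c(Dt, d[2], d[3]))
  th <- plan$tile[1]; tw <- plan$tile[2]
  for (zs in plan$z_starts) for (ys in plan$y_starts)
    for (xs in plan$x_starts) {
      cube <- nv[zs + seq_len(L), ys + seq_len(th), xs + seq_len(tw),
                 drop = FALSE]
      pred <- fwd(cube)
      zi <- zs * r + seq_len(Lt)
      acc[zi, ys + seq_len(th), xs + seq_len(tw)] <-
        acc[zi, ys + seq_len(th), xs + seq_len(tw)] + pred
      cnt[zi, ys + seq_len(th), xs + seq_len(tw)] <-
        cnt[zi, ys + seq_len(th), xs + seq_len(tw)] + 1
    }
  stopifnot(all(cnt > 0))
  out <- clamp_unit(acc / cnt)
  denormalize(ct_volume(out, spacing = c(thick$spacing[1] / r,
                                         thick$spacing[2:3]),
                        origin = thick$origin, space = "unit"))
}

# Catmull-Rom (a = -0.5) kernel value at distance t >= 0
catmull_rom <- function(t) {
  t <- abs(t)
  ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
         ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
}

# (D_out x D) interpolation matrix along z at positions k/r, with linear
# extrapolation one sample beyond each end so degree-1 signals are exact
bicubic_z_matrix <- function(D, r) {
  Dt <- (D - 1L) * r + 1L
  M <- matrix(0, Dt, D)
  addw <- function(row, j, w) {
    if (j < 0L) { M[row, 1] <<- M[row, 1] + 2 * w
                  M[row, 2] <<- M[row, 2] - w }
    else if (j >= D) { M[row, D] <<- M[row, D] + 2 * w
                       M[row, D - 1L] <<- M[row, D - 1L] - w }
    else M[row, j + 1L] <<- M[row, j + 1L] + w
  }
  for (k in seq_len(Dt) - 1L) {
    p <- k / r
    base <- floor(p); f <- p - base
    if (f == 0) { M[k + 1L, base + 1L] <- 1; next }
    for (j in (base - 1L):(base + 2L))
      addw(k + 1L, j, catmull_rom(p - j))
  }
  M
}

#' Bicubic interpolation baseline (BIS)
#'
#' One-dimensional bicubic (Catmull-Rom, a = -0.5) interpolation along the
#' axial axis at target positions `k / r` in thick-index coordinates.
#' Coincident positions reproduce the thick slices exactly and in-plane
#' values are untouched, mirroring resampling-tool behaviour.
#'
#' @param thick a `ct_volume` with at least 2 slices.
#' @param r integer upsampling factor.
#' @return A `ct_volume` with `(D - 1) * r + 1` slices.
#' @export
bicubic_baseline <- function(thick, r = 5L) {
  stopifnot(is_ct_volume(thick))
  d <- dim(thick$values)
  if (d[1] < 2L) stop("bicubic_baseline: need at least 2 slices")
  M <- bicubic_z_matrix(d[1], as.integer(r))
  out <- M %*% matrix(thick$values, d[1])
  ct_volume(array(out, c(nrow(M), d[2], d[3])),
            spacing = c(thick$spacing[1] / r, thick$spacing[2:3]),
            origin = thick$origin, space = thick$space)
}
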
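#' Configuration for the paired lung-phantom simulator
#'
#' The simulator emulates the kind of thin-slice chest CT the synthesis
#' model is trained on: an elliptical body shell containing two air-filled
#' lung fields, tubular vessels that drift through the axial direction,
#' thin fissure plates, and ellipsoidal nodules of the three radiological
#' kinds (solid, subsolid, calcific).  Its thick-slice counterpart is
#' produced by [degrade_to_thick()], so each phantom pair obeys the same
#' alignment law as clinical thin/thick reconstructions from identical raw
#' data: thick slice `i` coincides with thin slice `r*i`.
#'
#' @param shape_thin integer length-3 `(D_thin, H, W)`; `D_thin` must be
#'   `1 (mod 5)` so that `D_thin = (D_thick - 1) * 5 + 1`.
#' @param seed integer seed controlling all phantom randomness.
#' @param n_vessels,n_nodules,n_fissures structure counts.
#' @param nodule_kinds length-3 proportions for solid/subsolid/calcific
#'   nodules (normalized internally).
#' @param noise_sd Gaussian noise standard deviation in HU.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape_thin = c(41L, 64L, 64L), seed = 1L,
                           n_vessels = 10L, n_nodules = 4L, n_fissures = 1L,
                           nodule_kinds = c(solid = 0.5, subsolid = 0.2,
                                            calcific = 0.3),
                           noise_sd = 20) {
  shape_thin <- as.integer(shape_thin)
  if (length(shape_thin) != 3L || any(shape_thin < 1L))
    stop("shape_thin must be three positive integers (D_thin, H, W)")
  if (shape_thin[1] %% 5L != 1L)
    stop(sprintf(
      "D_thin = %d violates the pairing law: need D_thin = 1 (mod 5) so that D_thin = (D_thick - 1) * 5 + 1",
      shape_thin[1]))
  if (any(c(n_vessels, n_nodules, n_fissures) < 0L))
    stop("structure counts must be >= 0")
  if (length(nodule_kinds) != 3L || any(nodule_kinds < 0) ||
      sum(nodule_kinds) <= 0)
    stop("nodule_kinds must be three non-negative proportions")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(shape_thin = shape_thin, seed = as.integer(seed),
                 n_vessels = as.integer(n_vessels),
                 n_nodules = as.integer(n_nodules),
                 n_fissures = as.integer(n_fissures),
                 nodule_kinds = nodule_kinds / sum(nodule_kinds),
                 noise_sd = noise_sd),
            class = "phantom_config")
}

# evaluate code with a local RNG seed, restoring global state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

# HU palette (approximate clinical values)
.phantom_hu <- list(outside = -1000, body = 40, lung = -900, vessel = 50,
                    fissure = -700,
                    nodule = c(solid = 0, subsolid = -500, calcific = 800))

#' Generate a synthetic thin-slice lung phantom
#'
#' Deterministic given `cfg$seed`.  Structures are painted in HU, lightly
#' smoothed (sigma 0.3 voxel, separable Gaussian) to emulate the partial
#' volume of a reconstruction kernel, corrupted with Gaussian noise, and
#' clamped to `[-1024, 2048]`.  A provenance log (nodule centers, radii and
#' kinds; vessel seeds; fissure parameters) is attached as
#' `attr(, "provenance")`.
#'
#' @param cfg a [phantom_config()].
#' @return A `ct_volume` (thin geometry, `dz = 1`).
#' @export
synthesize_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_local_seed(cfg$seed, {
    d <- cfg$shape_thin
    D <- d[1]; H <- d[2]; W <- d[3]
    hu <- .phantom_hu
    vol <- array(hu$outside, c(D, H, W))

    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    body <- ((yy - cy) / (0.46 * H))^2 + ((xx - cx) / (0.46 * W))^2 <= 1
    lungL <- ((yy - cy) / (0.32 * H))^2 + ((xx - cx + 0.22 * W) /
                                             (0.17 * W))^2 <= 1
    lungR <- ((yy - cy) / (0.32 * H))^2 + ((xx - cx - 0.22 * W) /
                                             (0.17 * W))^2 <= 1
    lung <- lungL | lungR
    for (z in seq_len(D)) {
      sl <- vol[z, , ]
      sl[body] <- hu$body
      sl[lung] <- hu$lung
      vol[z, , ] <- sl
    }
    lung_idx <- which(lung, arr.ind = TRUE)

    # fissures: oblique planes through a lung, ~1 voxel thick
    fissures <- vector("list", cfg$n_fissures)
    for (k in seq_len(cfg$n_fissures)) {
      nrm <- c(stats::runif(1, 0.5, 1.2), 1, stats::runif(1, -0.4, 0.4))
      nrm <- nrm / sqrt(sum(nrm^2))
      p0 <- c(stats::runif(1, 0.3, 0.7) * D, cy + stats::runif(1, -4, 4),
              if (stats::runif(1) < 0.5) cx - 0.22 * W else cx + 0.22 * W)
      for (z in seq_len(D)) {
        dist <- nrm[1] * (z - p0[1]) + nrm[2] * (yy - p0[2]) +
          nrm[3] * (xx - p0[3])
        hit <- lung & abs(dist) < 0.8
        sl <- vol[z, , ]; sl[hit] <- hu$fissure; vol[z, , ] <- sl
      }
      fissures[[k]] <- list(normal = nrm, point = p0)
    }

    # vessels: tubes drifting through z inside a lung field; the drift is
    # what puts genuine sub-thick-slice structure into the z profiles
    vessels <- vector("list", cfg$n_vessels)
    for (k in seq_len(cfg$n_vessels)) {
      start <- lung_idx[sample.int(nrow(lung_idx), 1L), ]
      rad <- stats::runif(1, 0.8, 2.0)
      pos <- c(start[1], start[2])
      for (z in seq_len(D)) {
        pos <- pos + stats::rnorm(2, 0, 0.35)
        pos[1] <- min(max(pos[1], 2), H - 1)
        pos[2] <- min(max(pos[2], 2), W - 1)
        hit <- lung & ((yy - pos[1])^2 + (xx - pos[2])^2 <= rad^2)
        sl <- vol[z, , ]; sl[hit] <- hu$vessel; vol[z, , ] <- sl
      }
      vessels[[k]] <- list(start = as.integer(start), radius = rad)
    }

    # nodules: disjoint ellipsoids of the three kinds
    kinds <- names(cfg$nodule_kinds)
    nodules <- list()
    zz_line <- seq_len(D)
    for (k in seq_len(cfg$n_nodules)) {
      for (attempt in 1:200) {
        ctr <- c(stats::runif(1, 0.2, 0.8) * D,
                 lung_idx[sample.int(nrow(lung_idx), 1L), ])
        radii <- c(stats::runif(1, 2, 4.5), stats::runif(1, 2, 4.5),
                   stats::runif(1, 2, 4.5))
        ok <- TRUE
        for (nd in nodules) {
          gap <- sqrt(sum((ctr - nd$center)^2))
          if (gap < max(radii) + max(nd$radii) + 2) { ok <- FALSE; break }
        }
        if (ok) break
      }
      if (!ok) next
      kind <- sample(kinds, 1L, prob = cfg$nodule_kinds)
      val <- hu$nodule[[kind]]
      z_lo <- max(1L, floor(ctr[1] - radii[1]))
      z_hi <- min(D, ceiling(ctr[1] + radii[1]))
      for (z in z_lo:z_hi) {
        dist <- ((z - ctr[1]) / radii[1])^2 + ((yy - ctr[2]) / radii[2])^2 +
          ((xx - ctr[3]) / radii[3])^2
        hit <- lung & dist <= 1
        sl <- vol[z, , ]; sl[hit] <- val; vol[z, , ] <- sl
      }
      nodules[[length(nodules) + 1L]] <-
        list(center = ctr, radii = radii, kind = kind, hu = val)
    }

    vol <- gauss_smooth3(vol, sigma = 0.3)
    if (cfg$noise_sd > 0)
      vol <- vol + array(stats::rnorm(length(vol), 0, cfg$noise_sd), dim(vol))
    vol <- pmin(pmax(vol, .hu_min), .hu_max)

    out <- ct_volume(vol, spacing = c(1, 1, 1))
    attr(out, "provenance") <- list(seed = cfg$seed, nodules = nodules,
                                    vessels = vessels, fissures = fissures)
    out
  })
}

# separable Gaussian smoothing of a (Z,Y,X) array, reflected at edges
gauss_smooth3 <- function(a, sigma) {
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    d <- dim(a)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(a, perm), d[axis])
    n <- d[axis]
    idx <- outer(seq_len(n), -rad:rad, "+")
    idx <- abs(idx - 1L); idx <- n - 1L - abs(idx - (n - 1L)); idx <- idx + 1L
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    aperm(array(out, d[perm]), order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

# slice-sensitivity profiles: weights over thin-slice offsets -floor(r/2)..
ssp_weights <- function(r, profile = c("box", "triangle", "gaussian")) {
  profile <- match.arg(profile)
  half <- floor(r / 2)
  off <- -half:half
  w <- switch(profile,
              box = rep(1, length(off)),
              triangle = (half + 1) - abs(off),
              gaussian = stats::dnorm(off, sd = r / 2.355))
  list(offsets = off, weights = w / sum(w))
}

#' Degrade a thin-slice volume to its thick-slice counterpart
#'
#' Thick slice `i` (0-based) is the slice-sensitivity-profile weighted
#' average of the thin slices centered on the coincident thin slice
#' `r*i`, using a window of width r truncated (and renormalized) at the
#' volume ends.  The default box profile takes the plain mean of the thin
#' slices with z in `[r*i - floor(r/2), r*i + floor(r/2)]`.  In-plane values
#' are untouched; `dz` is multiplied by `r`.
#'
#' @param thin a `ct_volume` whose slice count is `1 (mod r)`.
#' @param r integer super-resolution factor (default 5).
#' @param profile `"box"` (default), `"triangle"` or `"gaussian"`.
#' @return A `ct_volume` with `(D_thin - 1) / r + 1` slices.
#' @export
degrade_to_thick <- function(thin, r = 5L, profile = "box") {
  stopifnot(is_ct_volume(thin))
  r <- as.integer(r)
  D_thin <- dim(thin$values)[1]
  if ((D_thin - 1L) %% r != 0L)
    stop(sprintf(
      "degrade_to_thick: thin slice count %d is not 1 (mod %d)", D_thin, r))
  D_thick <- (D_thin - 1L) %/% r + 1L
  sp <- ssp_weights(r, profile)
  d <- dim(thin$values)
  flat <- matrix(thin$values, d[1])  # slices x (H*W)
  out <- matrix(0, D_thick, ncol(flat))
  for (i in seq_len(D_thick)) {
    z <- (i - 1L) * r + 1L + sp$offsets
    keep <- z >= 1L & z <= D_thin
    w <- sp$weights[keep] / sum(sp$weights[keep])
    out[i, ] <- crossprod(w, flat[z[keep], , drop = FALSE])
  }
  ct_volume(array(out, c(D_thick, d[2], d[3])),
            spacing = c(thin$spacing[1] * r, thin$spacing[2:3]),
            origin = thin$origin, space = thin$space)
}

#' Generate a deterministic set of paired thin/thick phantoms
#'
#' Per-sample seeds are derived from `(seed, index)` so the dataset is
#' reproducible and samples are mutually distinct.
#'
#' @param n number of samples.
#' @param base_cfg a [phantom_config()] used for every sample (its seed is
#'   replaced per sample).
#' @param seed integer master seed.
#' @param r super-resolution factor.
#' @param profile slice-sensitivity profile passed to [degrade_to_thick()].
#' @return A list of `n` paired samples, each a list with elements `thin`,
#'   `thick` and `r`.
#' @export
make_paired_dataset <- function(n, base_cfg = phantom_config(), seed = 1L,
                                r = 5L, profile = "box") {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    cfg <- base_cfg
    cfg$seed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    thin <- synthesize_phantom(cfg)
    list(thin = thin, thick = degrade_to_thick(thin, r, profile),
         r = as.integer(r))
  })
}
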
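# Reverse-mode automatic differentiation on a dynamic tape.
#
# The synthesis network needs gradients for a few dozen array operations
# (linear maps, layer norm, windowed attention, small convolutions); no
# deep-learning framework ships with R, so this file provides a minimal
# tape.  A node is an environment holding `value` (a numeric array),
# `grad` (accumulated cotangent, NULL until touched), and `bw`, a closure
# that propagates `grad` to the node's parents.  Operations record nodes
# on a global tape only while `ag_with_tape()` is active; outside it they
# compute values only, which is what inference uses.

.ag <- new.env(parent = emptyenv())
.ag$on <- FALSE
.ag$tape <- NULL

ag_tensor <- function(value, param = FALSE) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$param <- param
  nd$bw <- NULL
  class(nd) <- "ag_tensor"
  nd
}

ag_value <- function(x) if (inherits(x, "ag_tensor")) x$value else x

ag_node <- function(value, bw = NULL) {
  nd <- ag_tensor(value)
  if (.ag$on && !is.null(bw)) {
    nd$bw <- bw
    .ag$tape[[length(.ag$tape) + 1L]] <- nd
  }
  nd
}

ag_accum <- function(nd, g) {
  if (is.null(nd$bw) && !nd$param) return(invisible(NULL))
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @keywords internal
ag_with_tape <- function(code) {
  old_on <- .ag$on; old_tape <- .ag$tape
  .ag$on <- TRUE; .ag$tape <- list()
  on.exit({ .ag$on <- old_on; .ag$tape <- old_tape }, add = TRUE)
  res <- code
  list(result = res, tape = .ag$tape)
}

# run backward over a recorded tape starting from scalar node `loss`
ag_backward <- function(taped) {
  loss <- taped$result
  loss$grad <- 1
  for (i in rev(seq_along(taped$tape))) {
    nd <- taped$tape[[i]]
    if (!is.null(nd$grad) && !is.null(nd$bw)) nd$bw(nd$grad)
  }
  invisible(NULL)
}

# ---- primitive operations -------------------------------------------------

# affine map over the last dimension of an arbitrary-rank array
ag_linear <- function(x, W, b = NULL) {
  xv <- x$value; Wv <- W$value
  d <- dim(xv); cin <- d[length(d)]
  n <- prod(d) / cin
  xf <- matrix(xv, n, cin)
  yf <- xf %*% Wv
  if (!is.null(b)) yf <- yf + rep(b$value, each = n)
  out_dim <- c(d[-length(d)], ncol(Wv))
  ag_node(array(yf, out_dim), bw = function(g) {
    gf <- matrix(g, n)
    ag_accum(W, crossprod(xf, gf))
    if (!is.null(b)) ag_accum(b, colSums(gf))
    ag_accum(x, array(tcrossprod(gf, Wv), d))
  })
}

ag_layernorm <- function(x, gam, bet, eps = 1e-5) {
  xv <- x$value; d <- dim(xv); cc <- d[length(d)]
  n <- prod(d) / cc
  fw <- layernorm_cpp(matrix(xv, n, cc), gam$value, bet$value, eps)
  ag_node(array(fw$y, d), bw = function(g) {
    bwd <- layernorm_bwd_cpp(matrix(g, n), fw$xhat, fw$inv, gam$value)
    ag_accum(gam, as.vector(bwd$dgamma))
    ag_accum(bet, as.vector(bwd$dbeta))
    ag_accum(x, array(bwd$dx, d))
  })
}

# sigmoid-approximated GELU (x * sigmoid(1.702 x)); one exp() per pass
ag_gelu <- function(x) {
  xv <- x$value
  s <- 1 / (1 + exp(-1.702 * xv))
  ag_node(xv * s, bw = function(g) {
    ag_accum(x, g * (s + 1.702 * xv * s * (1 - s)))
  })
}

ag_add <- function(a, b) {
  ag_node(a$value + b$value, bw = function(g) {
    ag_accum(a, g); ag_accum(b, g)
  })
}

ag_sub <- function(a, b) {
  ag_node(a$value - b$value, bw = function(g) {
    ag_accum(a, g); ag_accum(b, -g)
  })
}

ag_scale <- function(x, s) {
  ag_node(x$value * s, bw = function(g) ag_accum(x, g * s))
}

# add a constant array (e.g. an attention mask); no gradient to the constant
ag_add_const <- function(x, const) {
  ag_node(x$value + const, bw = function(g) ag_accum(x, g))
}

# geometry-keyed cache of precomputed permutation vectors
.perm_cache <- new.env(parent = emptyenv())

cached_perm <- function(key, builder) {
  p <- .perm_cache[[key]]
  if (is.null(p)) {
    p <- builder()
    p$inv <- integer(length(p$idx))
    p$inv[p$idx] <- seq_along(p$idx)
    .perm_cache[[key]] <- p
  }
  p
}

# apply a precomputed bijective index permutation (fused reshape+aperm)
ag_permute <- function(x, perm) {
  ag_node(array(x$value[perm$idx], perm$out_dim),
          bw = function(g) ag_accum(x, array(g[perm$inv], perm$gdim)))
}

# permutation vector realizing aperm(array(seq, in_dim), ap) -> out_dim;
# `gdim` are the dims the back-propagated gradient should carry (the
# upstream node's actual dims, when they differ from the factorization
# used to express the permutation)
build_perm <- function(in_dim, ap, out_dim, gdim = in_dim) {
  idx <- as.vector(aperm(array(seq_len(prod(in_dim)), in_dim), ap))
  list(idx = idx, in_dim = in_dim, out_dim = out_dim, gdim = gdim)
}

ag_reshape <- function(x, dims) {
  d0 <- dim(x$value)
  if (is.null(d0)) d0 <- length(x$value)
  ag_node(array(x$value, dims), bw = function(g) ag_accum(x, array(g, d0)))
}

ag_aperm <- function(x, perm) {
  ag_node(aperm(x$value, perm),
          bw = function(g) ag_accum(x, aperm(g, order(perm))))
}

# cyclic shift along the first three (spatial) axes of a rank-4 array
roll_arr4 <- function(a, sh) {
  d <- dim(a)
  ix <- lapply(1:3, function(k) {
    if (sh[k] %% d[k] == 0L) seq_len(d[k])
    else 1L + (seq_len(d[k]) - 1L - sh[k]) %% d[k]
  })
  a[ix[[1]], ix[[2]], ix[[3]], , drop = FALSE]
}

ag_roll <- function(x, sh) {
  ag_node(roll_arr4(x$value, sh),
          bw = function(g) ag_accum(x, roll_arr4(g, -sh)))
}

# zero-pad the three spatial axes of a rank-4 array up to `to` (at the end)
ag_pad3 <- function(x, to) {
  d <- dim(x$value)
  if (all(d[1:3] == to)) return(x)
  out <- array(0, c(to, d[4]))
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ] <- x$value
  ag_node(out, bw = function(g) {
    ag_accum(x, g[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), ,
                  drop = FALSE])
  })
}

ag_crop3 <- function(x, to) {
  d <- dim(x$value)
  if (all(d[1:3] == to)) return(x)
  ag_node(x$value[seq_len(to[1]), seq_len(to[2]), seq_len(to[3]), ,
                  drop = FALSE],
          bw = function(g) {
            gg <- array(0, d)
            gg[seq_len(to[1]), seq_len(to[2]), seq_len(to[3]), ] <- g
            ag_accum(x, gg)
          })
}

# batched matrix multiply on (rows, cols, batch) cubes via the C++ kernel
ag_bmm <- function(a, b, ta = FALSE, tb = FALSE) {
  av <- a$value; bv <- b$value
  ag_node(bmm_cpp(av, bv, ta, tb), bw = function(g) {
    if (!ta && !tb) {
      ag_accum(a, bmm_cpp(g, bv, FALSE, TRUE))
      ag_accum(b, bmm_cpp(av, g, TRUE, FALSE))
    } else if (!ta && tb) {
      ag_accum(a, bmm_cpp(g, bv, FALSE, FALSE))
      ag_accum(b, bmm_cpp(g, av, TRUE, FALSE))
    } else if (ta && !tb) {
      ag_accum(a, bmm_cpp(bv, g, FALSE, TRUE))
      ag_accum(b, bmm_cpp(av, g, FALSE, FALSE))
    } else {
      stop("ag_bmm: ta && tb unsupported")
    }
  })
}

# softmax over the second dimension of a (n, m, batch) array
ag_softmax2 <- function(x) {
  y <- softmax2_cpp(x$value)
  ag_node(y, bw = function(g) ag_accum(x, softmax2_bwd_cpp(g, y)))
}

# add relative-position bias to attention scores.
# scores: (w, w, nw * heads) with window index fastest within each head;
# table: (n_rel, heads) parameter; idx: (w, w) 1-based indices into rows.
ag_rpb <- function(scores, table, idx, nw, heads) {
  w <- dim(scores$value)[1]
  tv <- table$value
  bias <- array(tv[as.vector(idx), ], c(w, w, heads))
  full <- bias[, , rep(seq_len(heads), each = nw), drop = FALSE]
  ag_node(scores$value + full, bw = function(g) {
    dt <- matrix(0, nrow(tv), heads)
    for (h in seq_len(heads)) {
      gh <- g[, , (h - 1L) * nw + seq_len(nw), drop = FALSE]
      s2 <- rowSums(gh, dims = 2)
      agg <- rowsum(as.vector(s2), as.vector(idx))
      dt[as.integer(rownames(agg)), h] <- agg[, 1]
    }
    ag_accum(table, dt)
    ag_accum(scores, g)
  })
}

# shift a rank-4 array along given axes with zero fill
shift_zero4 <- function(a, sh) {
  d <- dim(a)
  out <- array(0, d)
  src <- dst <- vector("list", 4)
  for (k in 1:4) {
    s <- if (k <= 3) sh[k] else 0L
    if (s >= 0) { src[[k]] <- seq_len(d[k] - s); dst[[k]] <- seq_len(d[k] - s) + s }
    else { src[[k]] <- seq_len(d[k] + s) - s; dst[[k]] <- seq_len(d[k] + s) }
    if (d[k] - abs(s) <= 0) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]], dst[[4]]] <-
    a[src[[1]], src[[2]], src[[3]], src[[4]]]
  out
}

# cached zero-fill shift as an index map: out = c(x, 0)[idx]; the inverse
# map routes gradients back (dropped positions point at the zero slot)
cached_shift <- function(d, off) {
  key <- paste("sh", paste(d, collapse = ","), paste(off, collapse = ","))
  p <- .perm_cache[[key]]
  if (is.null(p)) {
    n <- prod(d)
    fwd <- as.vector(shift_zero4(array(seq_len(n), d), off))
    fwd[fwd == 0] <- n + 1L
    bwd <- as.vector(shift_zero4(array(seq_len(n), d), -off))
    bwd[bwd == 0] <- n + 1L
    p <- list(idx = as.integer(fwd), inv = as.integer(bwd))
    .perm_cache[[key]] <- p
  }
  p
}

# channel-preserving kernel-3 convolution over the axes in `axes`
# (subset of 1:3) of a (s1, s2, s3, C) feature array.  Implemented as one
# im2col matrix product: columns are the shifted copies of the input.
# W: (C, C, n_offsets); b: (C).
ag_conv <- function(x, W, b, axes) {
  xv <- x$value; d <- dim(xv); cc <- d[4]
  n <- prod(d[1:3])
  offs <- as.matrix(expand.grid(lapply(1:3, function(k)
    if (k %in% axes) -1:1 else 0L)))
  no <- nrow(offs)
  Wv <- W$value
  shifts <- lapply(seq_len(no), function(o) cached_shift(d, offs[o, ]))
  xv0 <- c(xv, 0)
  xcol <- matrix(0, n, cc * no)
  for (o in seq_len(no))
    xcol[, (o - 1L) * cc + seq_len(cc)] <- xv0[shifts[[o]]$idx]
  Wbig <- matrix(aperm(Wv, c(1, 3, 2)), cc * no, cc)  # rows: (channel, offset)
  yf <- xcol %*% Wbig + rep(b$value, each = n)
  ag_node(array(yf, d), bw = function(g) {
    gf <- matrix(g, n, cc)
    dWbig <- crossprod(xcol, gf)                       # (cc*no, cc)
    ag_accum(W, aperm(array(dWbig, c(cc, no, cc)), c(1, 3, 2)))
    ag_accum(b, colSums(gf))
    dxcol <- tcrossprod(gf, Wbig)                      # (n, cc*no)
    dx <- numeric(prod(d))
    for (o in seq_len(no)) {
      piece <- c(dxcol[, (o - 1L) * cc + seq_len(cc)], 0)
      dx <- dx + piece[shifts[[o]]$inv]
    }
    ag_accum(x, array(dx, d))
  })
}

# insert mask tokens between encoder slice features (Mask Token Add).
# latent: (L, Y, X, C); token: (C); pe: (r, C) phase embedding by z mod r.
ag_mask_scatter <- function(latent, token, pe, r) {
  lv <- latent$value; d <- dim(lv)
  L <- d[1]; Lt <- (L - 1L) * r + 1L
  phase <- (seq_len(Lt) - 1L) %% r + 1L     # 1 at coincident slices
  coin <- which(phase == 1L)                # z = r*i positions
  out <- array(0, c(Lt, d[2], d[3], d[4]))
  out[coin, , , ] <- lv
  tok_slice <- array(rep(token$value, each = d[2] * d[3]),
                     c(d[2], d[3], d[4]))
  for (z in which(phase != 1L)) out[z, , , ] <- tok_slice
  pev <- pe$value
  for (z in seq_len(Lt))
    out[z, , , ] <- out[z, , , ] +
      array(rep(pev[phase[z], ], each = d[2] * d[3]), c(d[2], d[3], d[4]))
  ag_node(out, bw = function(g) {
    ag_accum(latent, g[coin, , , , drop = FALSE])
    mk <- which(phase != 1L)
    if (length(mk))
      ag_accum(token, colSums(matrix(g[mk, , , , drop = FALSE],
                                     length(mk) * d[2] * d[3], d[4])))
    dpe <- matrix(0, r, d[4])
    for (ph in seq_len(r)) {
      zz <- which(phase == ph)
      dpe[ph, ] <- colSums(matrix(g[zz, , , , drop = FALSE],
                                  length(zz) * d[2] * d[3], d[4]))
    }
    ag_accum(pe, dpe)
  })
}

# mean absolute / squared error against a constant target
ag_loss <- function(pred, target, kind = c("l1", "l2")) {
  kind <- match.arg(kind)
  dv <- pred$value - target
  n <- length(dv)
  if (kind == "l1")
    ag_node(mean(abs(dv)), bw = function(g) ag_accum(pred, g * sign(dv) / n))
  else
    ag_node(mean(dv * dv), bw = function(g) ag_accum(pred, g * 2 * dv / n))
}
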
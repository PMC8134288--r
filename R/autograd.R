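# Minimal reverse-mode automatic differentiation over dense arrays.
#
# A tape records nodes in creation order; each node holds its value, an
# optional backward closure and the list of parent nodes. backward() walks
# the tape in reverse, accumulating gradients. Activations live in arrays
# with dims (H, W, C, N); parameters are leaves created per forward pass
# from the plain arrays stored in the network object, so there is no
# persistent graph state between steps.

new_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, val, parents = list(), backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$grad <- NULL
  nd$parents <- parents
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_leaf <- function(tape, val) ag_node(tape, val)

ag_backward <- function(tape, root) {
  root$grad <- if (length(root$val) == 1L) 1 else array(1, dim(root$val))
  for (i in rev(seq_len(tape$n))) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn)) next
    gs <- nd$backfn(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
  }
  invisible(root)
}

# ---- convolution ops --------------------------------------------------

# Convolution: x (H,W,Cin,N), W (kh,kw,Cin,Cout), b length Cout.
ag_conv <- function(tape, x, w, b, stride = 1L, pad = 0L) {
  d <- dim(x$val)
  dw <- dim(w$val)
  kh <- dw[1]; kw <- dw[2]; cin <- dw[3]; cout <- dw[4]
  if (d[3] != cin) stopf("ag_conv: input has %d channels, kernel expects %d",
                         d[3], cin)
  cols <- im2col_cpp(as.numeric(x$val), d[1], d[2], d[3], d[4],
                     kh, kw, stride, stride, pad, pad)
  Ho <- (d[1] + 2 * pad - kh) %/% stride + 1
  Wo <- (d[2] + 2 * pad - kw) %/% stride + 1
  Wm <- matrix(w$val, kh * kw * cin, cout)
  om <- crossprod(Wm, cols) + b$val
  val <- aperm(array(t(om), c(Ho, Wo, d[4], cout)), c(1, 2, 4, 3))
  ag_node(tape, val, list(x, w, b), function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), Ho * Wo * d[4], cout)
    dW <- array(cols %*% gm, dw)
    db <- colSums(gm)
    dcols <- Wm %*% t(gm)
    dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4],
                     kh, kw, stride, stride, pad, pad)
    list(array(dx, d), dW, db)
  })
}

# Transposed convolution: x (H,W,Cin,N), W (kh,kw,Cout,Cin), output
# ((H-1)*stride - 2*pad + kh, ...). With kh = 4, stride = 2, pad = 1 this
# exactly doubles the spatial size.
ag_tconv <- function(tape, x, w, b, stride = 2L, pad = 1L) {
  d <- dim(x$val)
  dw <- dim(w$val)
  kh <- dw[1]; kw <- dw[2]; cout <- dw[3]; cin <- dw[4]
  if (d[3] != cin) stopf("ag_tconv: input has %d channels, kernel expects %d",
                         d[3], cin)
  Ho <- (d[1] - 1) * stride - 2 * pad + kh
  Wo <- (d[2] - 1) * stride - 2 * pad + kw
  xm <- t(matrix(aperm(x$val, c(1, 2, 4, 3)), d[1] * d[2] * d[4], cin))
  Wm <- matrix(w$val, kh * kw * cout, cin)
  cols <- Wm %*% xm
  y <- col2im_cpp(cols, Ho, Wo, cout, d[4],
                  kh, kw, stride, stride, pad, pad)
  y <- y + rep(rep(b$val, each = Ho * Wo), times = d[4])
  val <- array(y, c(Ho, Wo, cout, d[4]))
  ag_node(tape, val, list(x, w, b), function(g) {
    gcols <- im2col_cpp(as.numeric(g), Ho, Wo, cout, d[4],
                        kh, kw, stride, stride, pad, pad)
    dxm <- crossprod(Wm, gcols)
    dx <- aperm(array(t(dxm), c(d[1], d[2], d[4], cin)), c(1, 2, 4, 3))
    dW <- array(gcols %*% t(xm), dw)
    db <- colSums(matrix(aperm(g, c(1, 2, 4, 3)), Ho * Wo * d[4], cout))
    list(dx, dW, db)
  })
}

# ---- elementwise ops --------------------------------------------------

ag_lrelu <- function(tape, x, alpha = 0.2) {
  slope <- (x$val > 0) * (1 - alpha) + alpha
  val <- x$val * slope
  ag_node(tape, val, list(x), function(g) list(g * slope))
}

ag_relu <- function(tape, x) ag_lrelu(tape, x, alpha = 0)

ag_tanh <- function(tape, x) {
  val <- tanh(x$val)
  ag_node(tape, val, list(x), function(g) list(g * (1 - val^2)))
}

# Multiply by a constant array (e.g. the fan mask, broadcast over C and N).
ag_mul_const <- function(tape, x, k) {
  d <- dim(x$val)
  kk <- if (length(dim(k)) == 2) array(k, d) else k
  val <- x$val * kk
  ag_node(tape, val, list(x), function(g) list(g * kk))
}

# ---- normalization and noise -----------------------------------------

# Instance normalization (no affine parameters): per channel and per batch
# element, subtract the spatial mean and divide by the spatial sd.
ag_instnorm <- function(tape, x, eps = 1e-5) {
  d <- dim(x$val)
  hw <- d[1] * d[2]
  xm <- matrix(x$val, hw, d[3] * d[4])
  mu <- colMeans(xm)
  xc <- xm - rep(mu, each = hw)
  v <- colMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  ym <- xc * rep(inv, each = hw)
  val <- array(ym, d)
  ag_node(tape, val, list(x), function(g) {
    gm <- matrix(g, hw, d[3] * d[4])
    gmu <- colMeans(gm)
    gyy <- colMeans(gm * ym)
    dx <- (gm - rep(gmu, each = hw) - ym * rep(gyy, each = hw)) *
      rep(inv, each = hw)
    list(array(dx, d))
  })
}

# StyleGAN-like noise injection: y[,,c,n] = x[,,c,n] + w[c] * z[,,1,n]
# where z is a fixed standard-normal image per batch element and w is a
# learned per-channel weight (a leaf of length C).
ag_add_noise <- function(tape, x, w, z) {
  d <- dim(x$val)
  wz <- array(0, d)
  for (cc in seq_len(d[3])) wz[, , cc, ] <- w$val[cc] * z[, , 1, ]
  val <- x$val + wz
  ag_node(tape, val, list(x, w), function(g) {
    dw <- vapply(seq_len(d[3]),
                 function(cc) sum(g[, , cc, ] * z[, , 1, ]), numeric(1))
    list(g, dw)
  })
}

# Concatenate nodes along the channel dimension.
ag_concat <- function(tape, xs) {
  ds <- lapply(xs, function(x) dim(x$val))
  chs <- vapply(ds, `[`, integer(1), 3L)
  d1 <- ds[[1]]
  val <- array(0, c(d1[1], d1[2], sum(chs), d1[4]))
  at <- 0L
  for (x in xs) {
    val[, , at + seq_len(dim(x$val)[3]), ] <- x$val
    at <- at + dim(x$val)[3]
  }
  ag_node(tape, val, xs, function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (k in seq_along(xs)) {
      out[[k]] <- g[, , at + seq_len(chs[k]), , drop = FALSE]
      at <- at + chs[k]
    }
    out
  })
}

# ---- losses -----------------------------------------------------------

# Mean absolute difference against a constant target array.
ag_l1_const <- function(tape, x, target) {
  diff <- x$val - target
  val <- mean(abs(diff))
  ag_node(tape, val, list(x),
          function(g) list(g * sign(diff) / length(diff)))
}

# Mean binary cross-entropy from logits, computed stably in logit space.
# target_real = TRUE pushes the logits towards "real" (label 1).
ag_bce_mean <- function(tape, x, target_real) {
  l <- x$val
  sp <- function(t) ifelse(t > 30, t, log1p(exp(pmin(t, 30))))
  if (target_real) {
    val <- mean(sp(-l))
    back <- function(g) list(g * (-1 / (1 + exp(l))) / length(l))
  } else {
    val <- mean(sp(l))
    back <- function(g) list(g * (1 / (1 + exp(-l))) / length(l))
  }
  ag_node(tape, val, list(x), back)
}

# a*x + b*y for scalar nodes (loss assembly).
ag_axpby <- function(tape, a, x, b, y) {
  ag_node(tape, a * x$val + b * y$val, list(x, y),
          function(g) list(g * a, g * b))
}
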
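# Shared internal helpers: seeding, array plumbing, resampling.

# Deterministic per-record seed from (seed, index): a 32-bit multiplicative
# mix (Knuth constant) carried out exactly in double arithmetic and reduced
# mod 2^31 - 1 so the result is always a valid positive R integer seed.
mix_seed <- function(seed, index) {
  m <- 2^31 - 1
  a <- (as.numeric(seed) %% m) * 2654435761 %% m
  b <- (as.numeric(index) %% m) * 40503 %% m
  as.integer((a + b + 12345) %% m)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bind a list of equally-shaped (H, W, C) arrays along a new batch dim.
bind_batch <- function(xs) {
  d <- dim(xs[[1]])
  array(unlist(xs, use.names = FALSE), c(d, length(xs)))
}

# One-hot encode an integer label matrix into an (H, W, n_labels) array.
one_hot <- function(s, labels) {
  H <- nrow(s); W <- ncol(s)
  out <- array(0, c(H, W, length(labels)))
  for (k in seq_along(labels)) out[, , k] <- (s == labels[k]) * 1
  out
}

# Block-average pooling of an (H, W, C[, N]) array by integer factor f.
pool_avg <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  H <- d[1]; W <- d[2]; rest <- prod(d[-(1:2)])
  H2 <- H %/% f; W2 <- W %/% f
  x <- array(x, c(H, W, rest))
  m <- array(x, c(f, H2 * W * rest))
  s1 <- array(colMeans(m), c(H2, W, rest))
  s1 <- aperm(s1, c(2, 1, 3))                       # (W, H2, rest)
  m2 <- array(s1, c(f, W2 * H2 * rest))
  s2 <- array(colMeans(m2), c(W2, H2, rest))
  out <- aperm(s2, c(2, 1, 3))
  array(out, c(H2, W2, d[-(1:2)]))
}

# Nearest-neighbour subsampling by factor f (categorical-safe).
pool_nearest <- function(x, f) {
  if (f == 1L) return(x)
  d <- dim(x)
  off <- (f + 1L) %/% 2L
  ih <- seq(off, d[1], by = f)[seq_len(d[1] %/% f)]
  iw <- seq(off, d[2], by = f)[seq_len(d[2] %/% f)]
  if (length(d) == 2) x[ih, iw, drop = FALSE]
  else if (length(d) == 3) x[ih, iw, , drop = FALSE]
  else x[ih, iw, , , drop = FALSE]
}

# Bilinear sampling of matrix `img` at fractional (row, col) positions.
# Out-of-range positions return `fill`.
bilinear_sample <- function(img, rf, cf, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  ok <- rf >= 1 & rf <= H & cf >= 1 & cf <= W
  r0 <- pmin(pmax(floor(rf), 1), H - 1); c0 <- pmin(pmax(floor(cf), 1), W - 1)
  fr <- rf - r0; fc <- cf - c0
  fr <- pmin(pmax(fr, 0), 1); fc <- pmin(pmax(fc, 0), 1)
  v <- img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
  v[!ok] <- fill
  v
}

# Resize a matrix to (H2, W2) by bilinear interpolation (used by feature
# extractors; not gradient-tracked).
resize_bilinear <- function(img, H2, W2) {
  H <- nrow(img); W <- ncol(img)
  rf <- (seq_len(H2) - 0.5) * H / H2 + 0.5
  cf <- (seq_len(W2) - 0.5) * W / W2 + 0.5
  rf <- pmin(pmax(rf, 1), H); cf <- pmin(pmax(cf, 1), W)
  g <- expand.grid(r = rf, c = cf)
  matrix(bilinear_sample(img, g$r, g$c), H2, W2)
}

# Reflect-pad a matrix by (pr, pc) on each side.
pad_reflect <- function(x, pr, pc) {
  H <- nrow(x); W <- ncol(x)
  ri <- c(rev(seq_len(min(pr, H - 1)) + 1), seq_len(H),
          H - seq_len(min(pr, H - 1)))
  ci <- c(rev(seq_len(min(pc, W - 1)) + 1), seq_len(W),
          W - seq_len(min(pc, W - 1)))
  x[ri, ci, drop = FALSE]
}

# 2-D correlation of matrix x with kernel k, "same" size, reflect boundary.
conv2_same <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  ph <- kh %/% 2; pw <- kw %/% 2
  xp <- pad_reflect(x, ph, pw)
  Hp <- nrow(xp); Wp <- ncol(xp)
  cols <- im2col_cpp(as.numeric(xp), Hp, Wp, 1L, 1L,
                     kh, kw, 1L, 1L, 0L, 0L)
  out <- crossprod(matrix(as.numeric(k), kh * kw, 1), cols)
  Ho <- Hp - kh + 1; Wo <- Wp - kw + 1
  m <- matrix(out, Ho, Wo)
  m[seq_len(nrow(x)) + (ph - kh %/% 2), seq_len(ncol(x)) + (pw - kw %/% 2),
    drop = FALSE]
}
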
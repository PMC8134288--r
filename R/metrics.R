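# Evaluation suite: PSNR, masked MAE, patch chi-squared local histogram
# metric with spatial error maps, and Frechet distance on pluggable
# image features.

#' Peak signal-to-noise ratio
#'
#' Uses a linear peak by default, `10 log10(255 / MSE)`; `peak = "squared"`
#' gives the conventional `255^2` numerator (24.07 dB higher). Every report
#' records which variant was used. Returns `Inf` for identical images.
#'
#' @param y,y_hat Images, same shape, 8-bit range.
#' @param peak `"linear"` (255) or `"squared"` (255^2).
#' @return Decibel value.
#' @export
psnr <- function(y, y_hat, peak = c("linear", "squared")) {
  peak <- match.arg(peak)
  if (!all(dim(y) == dim(y_hat))) stopf("psnr: shape mismatch")
  mse <- mean((as.numeric(y) - as.numeric(y_hat))^2)
  if (mse == 0) return(Inf)
  num <- if (peak == "linear") 255 else 255^2
  10 * log10(num / mse)
}

#' Mean absolute error
#'
#' Mean absolute pixel difference, restricted to the fan mask when given.
#'
#' @param y,y_hat Images, same shape.
#' @param mask Optional binary mask.
#' @return Scalar MAE.
#' @export
mae <- function(y, y_hat, mask = NULL) {
  if (!all(dim(y) == dim(y_hat))) stopf("mae: shape mismatch")
  d <- abs(as.numeric(y) - as.numeric(y_hat))
  if (is.null(mask)) mean(d) else mean(d[as.logical(mask)])
}

#' Intensity histogram over [0, 255]
#'
#' @param x Pixel values.
#' @param bins Number of equal-width bins (default 50).
#' @param normalize Normalize counts to sum 1.
#' @return Numeric vector of length `bins`.
#' @export
intensity_hist <- function(x, bins = 50L, normalize = TRUE) {
  idx <- pmin(pmax(floor(as.numeric(x) / 256 * bins), 0), bins - 1) + 1
  h <- tabulate(idx, nbins = bins)
  if (normalize && sum(h) > 0) h / sum(h) else h
}

#' Chi-squared distance between histograms
#'
#' `chi2(hA, hB) = 1/2 sum (hA - hB)^2 / (hA + hB)`, with bins where the
#' denominator is 0 skipped. Symmetric, non-negative, and at most 1 for
#' normalized histograms (exactly 1 for disjoint supports).
#'
#' @param hA,hB Histograms with equal bin count.
#' @return Scalar distance.
#' @export
chi2_hist <- function(hA, hB) {
  if (length(hA) != length(hB)) stopf("chi2_hist: bin-count mismatch")
  s <- hA + hB
  keep <- s > 0
  0.5 * sum((hA[keep] - hB[keep])^2 / s[keep])
}

#' Patch chi-squared local histogram metric
#'
#' Tiles both images into non-overlapping `patch x patch` patches anchored
#' at the top-left (incomplete border tiles dropped), computes normalized
#' `bins`-bin intensity histograms per patch and their chi-squared
#' distance, and reports the root mean square over patches that intersect
#' the mask. The spatial map holds the per-patch values (in `[0, 1]`) on
#' the tile grid.
#'
#' @param y,y_hat Images, same shape, 8-bit range.
#' @param patch Patch side (default 20).
#' @param bins Histogram bins (default 50).
#' @param mask Optional binary mask; patches not intersecting it are
#'   excluded from the scalar (the map is computed everywhere).
#' @return A `usgan_pchi2` list: `value` (scalar) and `map` (matrix).
#' @export
pchi2 <- function(y, y_hat, patch = 20L, bins = 50L, mask = NULL) {
  if (!all(dim(y) == dim(y_hat))) stopf("pchi2: shape mismatch")
  H <- nrow(y); W <- ncol(y)
  nr <- H %/% patch; nc <- W %/% patch
  if (nr < 1 || nc < 1) stopf("pchi2: image smaller than one %dx%d patch", patch, patch)
  map <- matrix(0, nr, nc)
  keep <- matrix(TRUE, nr, nc)
  for (i in seq_len(nr)) {
    ri <- (i - 1) * patch + seq_len(patch)
    for (j in seq_len(nc)) {
      ci <- (j - 1) * patch + seq_len(patch)
      map[i, j] <- chi2_hist(intensity_hist(y[ri, ci], bins),
                             intensity_hist(y_hat[ri, ci], bins))
      if (!is.null(mask)) keep[i, j] <- any(mask[ri, ci] > 0)
    }
  }
  structure(list(value = sqrt(mean(map[keep]^2)), map = map,
                 patch = patch, bins = bins),
            class = "usgan_pchi2")
}

#' Frechet distance between Gaussian fits of two feature sets
#'
#' `d2 = |mu1 - mu2|^2 + Tr(S1 + S2 - 2 (S1 S2)^(1/2))`, with the matrix
#' square root computed via the symmetric form `S1^(1/2) S2 S1^(1/2)` and
#' negative eigenvalues clipped at 0; a small diagonal regularizer guards
#' degenerate covariances.
#'
#' @param features_real,features_gen Matrices (rows = samples) of equal
#'   column dimension, each with >= 2 rows.
#' @param reg Diagonal regularizer added to both covariances.
#' @return Scalar Frechet distance (squared).
#' @export
fid <- function(features_real, features_gen, reg = 1e-6) {
  f1 <- as.matrix(features_real); f2 <- as.matrix(features_gen)
  if (ncol(f1) != ncol(f2)) stopf("fid: feature dimension mismatch")
  if (nrow(f1) < 2 || nrow(f2) < 2) stopf("fid: need >= 2 vectors per set")
  m1 <- colMeans(f1); m2 <- colMeans(f2)
  S1 <- stats::cov(f1) + diag(reg, ncol(f1))
  S2 <- stats::cov(f2) + diag(reg, ncol(f2))
  sqrtm_sym <- function(S) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  S1h <- sqrtm_sym(S1)
  M <- S1h %*% S2 %*% S1h
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tr_sqrt <- sum(sqrt(pmax(ev, 0)))
  sum((m1 - m2)^2) + sum(diag(S1)) + sum(diag(S2)) - 2 * tr_sqrt
}

#' Crop protocol for distribution-level evaluation
#'
#' Takes the center `512f x 512f` crop of a full field-of-view image and
#' divides it into four corner-anchored `299f x 299f` sub-crops
#' (overlapping, since 2 x 299 > 512). `factor = 1` reproduces the
#' full-scale protocol; smaller images use a proportional common factor.
#'
#' @param image Matrix.
#' @param factor Common scale factor; `NULL` picks
#'   `min(1, min(dim(image)) / 512)`.
#' @return List of four crop matrices, with attribute `offsets` (0-based
#'   corner coordinates within the center crop) and `sizes`.
#' @export
fid_crops <- function(image, factor = NULL) {
  H <- nrow(image); W <- ncol(image)
  factor <- factor %||% min(1, min(H, W) / 512)
  cs <- round(512 * factor); ss <- round(299 * factor)
  if (cs < 1 || ss < 1 || H < cs || W < cs)
    stopf("fid_crops: image %dx%d too small for a %d center crop", H, W, cs)
  r0 <- (H - cs) %/% 2; c0 <- (W - cs) %/% 2
  center <- image[r0 + seq_len(cs), c0 + seq_len(cs), drop = FALSE]
  off <- cs - ss
  corners <- list(c(0, 0), c(0, off), c(off, 0), c(off, off))
  crops <- lapply(corners, function(o)
    center[o[1] + seq_len(ss), o[2] + seq_len(ss), drop = FALSE])
  attr(crops, "offsets") <- do.call(rbind, corners)
  attr(crops, "sizes") <- c(center = cs, sub = ss)
  crops
}

#' Image feature extractors for distribution metrics
#'
#' `"random-projection"` (default): images are bilinearly resized to
#' `input_size^2`, flattened, and projected with a fixed seeded Gaussian
#' matrix to `dim` features — deterministic and training-free, suitable as
#' the test-time feature space. `"histogram-moments"`: intensity mean, sd,
#' and a 16-bin normalized histogram. `"inception-v3"` requires external
#' pretrained weights and raises an explicit error here (never a silent
#' fallback).
#'
#' @param kind Extractor name.
#' @param dim Feature dimension (random projection).
#' @param seed Seed of the projection matrix.
#' @param input_size Resize target for the projection extractor.
#' @return A function mapping a list of matrices (or a single matrix) to
#'   an `N x k` feature matrix.
#' @export
feature_extractor <- function(kind = c("random-projection",
                                       "histogram-moments", "inception-v3"),
                              dim = 64L, seed = 1L, input_size = 32L) {
  kind <- match.arg(kind)
  if (kind == "inception-v3")
    stopf(paste("inception-v3 features require pretrained weights that are",
                "not bundled; use 'random-projection' or supply features",
                "to fid() directly"))
  if (kind == "random-projection") {
    k <- input_size^2
    P <- withr::with_seed(as.integer(seed),
                          matrix(rnorm(k * dim, 0, 1 / sqrt(k)), k, dim))
    function(images) {
      if (is.matrix(images)) images <- list(images)
      v <- vapply(images, function(im)
        as.numeric(resize_bilinear(im / 255, input_size, input_size)),
        numeric(k))
      t(v) %*% P
    }
  } else {
    function(images) {
      if (is.matrix(images)) images <- list(images)
      t(vapply(images, function(im) {
        x <- as.numeric(im)
        c(mean = mean(x), sd = stats::sd(x) * sqrt((length(x) - 1) / length(x)),
          intensity_hist(x, bins = 16L))
      }, numeric(18)))
    }
  }
}

#' Per-image metric report
#'
#' Computes PSNR, masked MAE and patch chi-squared for each prediction /
#' target pair, plus set-level Frechet distance on the configured feature
#' extractor. Aggregates (mean, sd) are recomputable from the per-image
#' entries.
#'
#' @param pred,target Lists of 8-bit image matrices (equal length).
#' @param mask Binary fan mask shared by all images (or `NULL`).
#' @param patch,bins Patch chi-squared parameters.
#' @param extractor A [feature_extractor()] (or `NULL` to skip FID).
#' @param psnr_peak Passed to [psnr()].
#' @return A `usgan_report`: `per_image` tibble, `fid`, `summary` tibble.
#' @export
metric_report <- function(pred, target, mask = NULL, patch = 20L, bins = 50L,
                          extractor = feature_extractor(), psnr_peak = "linear") {
  stopifnot(length(pred) == length(target))
  rows <- lapply(seq_along(pred), function(i) {
    pc <- pchi2(target[[i]], pred[[i]], patch, bins, mask)
    tibble::tibble(image = i,
                   psnr = psnr(target[[i]], pred[[i]], psnr_peak),
                   mae = mae(target[[i]], pred[[i]], mask),
                   pchi2 = pc$value)
  })
  per_image <- dplyr::bind_rows(rows)
  fid_val <- if (!is.null(extractor) && length(pred) >= 2)
    fid(extractor(target), extractor(pred)) else NA_real_
  smry <- tibble::tibble(
    metric = c("psnr", "mae", "pchi2"),
    mean = vapply(per_image[c("psnr", "mae", "pchi2")], mean, numeric(1)),
    sd = vapply(per_image[c("psnr", "mae", "pchi2")], sd, numeric(1)))
  structure(list(per_image = per_image, fid = fid_val, summary = smry,
                 psnr_peak = psnr_peak),
            class = "usgan_report")
}

#' @export
print.usgan_report <- function(x, ...) {
  cat(sprintf("<usgan_report> %d images (PSNR formula: %s)\n",
              nrow(x$per_image), x$psnr_peak))
  print(x$summary)
  cat(sprintf("FID (feature space): %.4f\n", x$fid))
  invisible(x)
}

#' Paired per-image metric differences against a baseline variant
#'
#' @param per_image Tibble with columns `variant`, `image`, and metric
#'   columns (as produced by [run_ablation()]).
#' @param baseline Variant each other variant is compared to.
#' @return Tibble of per-image differences (variant minus baseline).
#' @export
paired_differences <- function(per_image, baseline = "SA2H") {
  base <- per_image[per_image$variant == baseline,
                    c("image", "psnr", "mae", "pchi2")]
  oth <- per_image[per_image$variant != baseline, ]
  j <- dplyr::inner_join(oth, base, by = "image", suffix = c("", "_base"))
  tibble::tibble(variant = j$variant, image = j$image,
                 d_psnr = j$psnr - j$psnr_base,
                 d_mae = j$mae - j$mae_base,
                 d_pchi2 = j$pchi2 - j$pchi2_base)
}

#' Shadow mask from a normalized attenuation map
#'
#' Marks pixels whose transmission falls below `ratio` times the same-depth
#' median inside the fan — i.e. columns locally darkened relative to their
#' depth peers, which is how bone shadows manifest after normalization.
#'
#' @param a Normalized Cartesian attenuation map.
#' @param mask Fan mask.
#' @param ratio Relative threshold (default 0.6).
#' @return Binary matrix.
#' @export
shadow_mask <- function(a, mask, ratio = 0.6) {
  out <- matrix(0, nrow(a), ncol(a))
  for (r in seq_len(nrow(a))) {
    in_fan <- mask[r, ] > 0
    if (!any(in_fan)) next
    med <- stats::median(a[r, in_fan])
    if (med <= 0) next
    out[r, ] <- (a[r, ] < ratio * med) & in_fan
  }
  out
}

#' Column-mean intensity correlation below bone
#'
#' For frames containing bone, correlates the per-column mean intensity of
#' prediction and reference over the rows below the deepest bone pixel
#' (inside the fan): a high correlation means the prediction darkens the
#' same columns the reference shadows.
#'
#' @param pred,ref 8-bit image matrices.
#' @param s Cartesian label map of the frame.
#' @param mask Fan mask.
#' @param bone_label Bone tissue code.
#' @return Correlation, or `NA` if the frame has no bone or too few columns.
#' @export
shadow_profile_correlation <- function(pred, ref, s, mask, bone_label = 4L) {
  br <- which(s == bone_label, arr.ind = TRUE)
  if (nrow(br) == 0) return(NA_real_)
  r0 <- min(nrow(s), max(br[, 1]) + 2L)
  if (r0 >= nrow(s) - 2) return(NA_real_)
  rows <- r0:nrow(s)
  cols <- which(colSums(mask[rows, , drop = FALSE]) >= length(rows) * 0.5)
  if (length(cols) < 8) return(NA_real_)
  cm <- function(img) vapply(cols, function(cc) {
    v <- img[rows, cc][mask[rows, cc] > 0]
    mean(v)
  }, numeric(1))
  p <- cm(pred); r <- cm(ref)
  if (sd(p) == 0 || sd(r) == 0) return(NA_real_)
  cor(p, r)
}
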
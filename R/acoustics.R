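#' Convex-probe imaging geometry
#'
#' Defines the mapping between the beam-aligned (polar) grid and the
#' Cartesian display raster of a convex transducer. The virtual apex sits
#' `probe_radius_cm` behind the skin line; a scanline at steering angle
#' theta reaches from range `probe_radius_cm` to `probe_radius_cm +
#' depth_cm`. Scanlines are ordered left-to-right by increasing angle.
#'
#' @param fov_deg Sector angle in degrees (0 < fov < 180). Default 70.
#' @param depth_cm Imaging depth in cm. Default 15.
#' @param probe_radius_cm Convex transducer radius in cm (0 gives a pure
#'   sector probe with the apex on the skin).
#' @param n_axial,n_lines Polar grid size.
#' @param out_shape Cartesian raster `c(rows, cols)`; `NULL` chooses a
#'   tight bounding raster with square pixels and `n_axial` rows.
#' @return A `usgan_fan_geometry` list.
#' @export
fan_geometry <- function(fov_deg = 70, depth_cm = 15, probe_radius_cm = 4,
                         n_axial = 64L, n_lines = 64L, out_shape = NULL) {
  if (fov_deg <= 0 || fov_deg >= 180) stopf("fan_geometry: need 0 < fov_deg < 180")
  if (depth_cm <= 0) stopf("fan_geometry: depth_cm must be positive")
  if (probe_radius_cm < 0) stopf("fan_geometry: probe_radius_cm must be >= 0")
  f <- fov_deg * pi / 180
  R <- probe_radius_cm; d <- depth_cm
  z0 <- R * cos(f / 2)          # top of the imaged region
  z1 <- R + d
  half_w <- (R + d) * sin(f / 2)
  if (is.null(out_shape)) {
    # raster dims rounded up to multiples of 16 so frames divide cleanly
    # through up to 4 stride-2 stages; the extra margin lies outside the fan
    h <- as.integer(16 * ceiling(n_axial / 16))
    px <- (z1 - z0) / h
    w <- as.integer(16 * ceiling(2 * half_w / px / 16))
    half_w <- w * px / 2
    out_shape <- c(h, w)
  }
  g <- list(fov_deg = fov_deg, depth_cm = depth_cm,
            probe_radius_cm = probe_radius_cm,
            n_axial = as.integer(n_axial), n_lines = as.integer(n_lines),
            out_shape = as.integer(out_shape),
            fov_rad = f, z_top = z0, z_bot = z1, half_width = half_w,
            cache = new.env(parent = emptyenv()))
  class(g) <- "usgan_fan_geometry"
  g
}

# Precompute (and cache) the inverse mapping from Cartesian raster pixels to
# fractional polar coordinates, plus the fan mask.
fan_mapping <- function(g) {
  if (!is.null(g$cache$map)) return(g$cache$map)
  H <- g$out_shape[1]; W <- g$out_shape[2]
  z <- g$z_top + (seq_len(H) - 0.5) / H * (g$z_bot - g$z_top)
  x <- (-g$half_width) + (seq_len(W) - 0.5) / W * (2 * g$half_width)
  zz <- matrix(z, H, W)
  xx <- matrix(x, H, W, byrow = TRUE)
  r <- sqrt(xx^2 + zz^2)
  th <- atan2(xx, zz)
  R <- g$probe_radius_cm
  inside <- r >= R & r <= R + g$depth_cm & abs(th) <= g$fov_rad / 2
  rf <- 1 + (r - R) / g$depth_cm * (g$n_axial - 1)
  cf <- 1 + (th + g$fov_rad / 2) / g$fov_rad * (g$n_lines - 1)
  map <- list(inside = inside, rf = rf, cf = cf)
  g$cache$map <- map
  map
}

#' Binary fan mask of a geometry
#'
#' @param g A [fan_geometry()].
#' @return Binary matrix over the Cartesian raster: 1 exactly where the
#'   polar preimage lies within the imaged sector.
#' @export
fan_mask <- function(g) {
  m <- fan_mapping(g)
  (m$inside) * 1
}

#' Per-pixel attenuation coefficient map
#'
#' Element-wise substitution of each tissue code by its attenuation
#' coefficient from the LUT.
#'
#' @param s Label map (integer matrix, polar grid).
#' @param lut Tissue LUT.
#' @return Numeric matrix of `mu` values (per axial sample).
#' @export
mu_map <- function(s, lut) lut_lookup(s, lut, "mu")

#' Integral attenuation (cumulative transmission) map
#'
#' Computes `a[z, x] = exp(-sum(mu[0..z, x]))` down each polar column with an
#' inclusive cumulative sum: row z includes its own attenuation. Values lie
#' in `(0, 1]` and are non-increasing with depth within each column.
#'
#' @param mu Non-negative attenuation coefficient matrix (polar).
#' @return A `usgan_attenuation` matrix with attribute `normalized = FALSE`.
#' @export
integral_attenuation <- function(mu) {
  if (any(mu < 0)) stopf("integral_attenuation: mu must be non-negative")
  a <- exp(-apply(mu, 2, cumsum))
  if (is.null(dim(a))) a <- matrix(a, 1)   # single-row input
  structure(a, normalized = FALSE, class = c("usgan_attenuation", "matrix", "array"))
}

#' Percentile normalization of an attenuation map
#'
#' Divides by the p-th linear-interpolation percentile of the flattened map
#' and clips to `[0, 1]`, making the map a valid network input. Performed
#' per image, before scan conversion.
#'
#' @param a Unnormalized attenuation map.
#' @param p Percentile (default 98).
#' @return Normalized `usgan_attenuation` in `[0, 1]`.
#' @export
normalize_attenuation <- function(a, p = 98) {
  if (isTRUE(attr(a, "normalized")))
    stopf("normalize_attenuation: map is already normalized")
  q <- unname(quantile(as.numeric(a), p / 100, type = 7))
  if (q == 0) stopf("normalize_attenuation: %g%%ile is zero (degenerate map)", p)
  out <- pmin(pmax(unclass(a) / q, 0), 1)
  structure(out, normalized = TRUE, class = c("usgan_attenuation", "matrix", "array"))
}

#' Scan conversion (polar to Cartesian, bilinear)
#'
#' Inverse-mapping interpolation: each Cartesian pixel inside the fan
#' samples the polar image bilinearly at its (range, angle) preimage;
#' pixels outside the fan are 0 and masked.
#'
#' @param polar Numeric matrix `(n_axial, n_lines)`.
#' @param g A [fan_geometry()].
#' @return List with `cartesian` (matrix `out_shape`) and `mask`.
#' @export
scan_convert <- function(polar, g) {
  if (!all(dim(polar) == c(g$n_axial, g$n_lines)))
    stopf("scan_convert: polar shape (%d, %d) does not match geometry (%d, %d)",
          nrow(polar), ncol(polar), g$n_axial, g$n_lines)
  m <- fan_mapping(g)
  H <- g$out_shape[1]; W <- g$out_shape[2]
  out <- matrix(0, H, W)
  idx <- which(m$inside)
  out[idx] <- bilinear_sample(unclass(polar), m$rf[idx], m$cf[idx])
  list(cartesian = out, mask = m$inside * 1)
}

#' Scan conversion for label maps (nearest neighbour)
#'
#' As [scan_convert()] but with nearest-neighbour sampling so output labels
#' are a subset of input labels (no intensity blending of categories).
#'
#' @inheritParams scan_convert
#' @export
scan_convert_nearest <- function(polar, g) {
  if (!all(dim(polar) == c(g$n_axial, g$n_lines)))
    stopf("scan_convert_nearest: polar shape does not match geometry")
  m <- fan_mapping(g)
  H <- g$out_shape[1]; W <- g$out_shape[2]
  out <- matrix(0, H, W)
  idx <- which(m$inside)
  ri <- pmin(pmax(round(m$rf[idx]), 1), g$n_axial)
  ci <- pmin(pmax(round(m$cf[idx]), 1), g$n_lines)
  out[idx] <- unclass(polar)[cbind(ri, ci)]
  storage.mode(out) <- storage.mode(polar)
  list(cartesian = out, mask = m$inside * 1)
}

#' Save / load an attenuation map
#'
#' PNG stores the map scaled by 255 into 8 bits; TIFF stores lossless
#' 32-bit float samples.
#'
#' @param a Attenuation map (values in `[0, 1]` for PNG).
#' @param path Output path; the extension (`.png` or `.tif`/`.tiff`)
#'   selects the format.
#' @return `save_attenuation` returns `path` invisibly;
#'   `load_attenuation` the numeric matrix.
#' @export
save_attenuation <- function(a, path) {
  m <- unclass(a)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(pmin(pmax(m, 0), 1), path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(m, path, bits.per.sample = 32)
  } else stopf("save_attenuation: use a .png or .tif/.tiff path")
  invisible(path)
}

#' @rdname save_attenuation
#' @export
load_attenuation <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE))
    png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

# Inverse resampler (Cartesian back to polar, bilinear); used for
# round-trip checks and shadow diagnostics on converted frames.
polar_resample <- function(cartesian, g) {
  H <- g$out_shape[1]; W <- g$out_shape[2]
  i <- matrix(seq_len(g$n_axial), g$n_axial, g$n_lines)
  j <- matrix(seq_len(g$n_lines), g$n_axial, g$n_lines, byrow = TRUE)
  r <- g$probe_radius_cm + (i - 1) / (g$n_axial - 1) * g$depth_cm
  th <- -g$fov_rad / 2 + (j - 1) / (g$n_lines - 1) * g$fov_rad
  x <- r * sin(th); z <- r * cos(th)
  rf <- (z - g$z_top) / (g$z_bot - g$z_top) * H + 0.5
  cf <- (x + g$half_width) / (2 * g$half_width) * W + 0.5
  matrix(bilinear_sample(cartesian, as.numeric(rf), as.numeric(cf)),
         g$n_axial, g$n_lines)
}
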
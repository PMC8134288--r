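#' Generate a paired (s, a, y) training dataset
#'
#' Emulates the paired corpus the translation network is trained on: for
#' each record a phantom is drawn on the polar grid, its normalized
#' integral attenuation map is computed, both are scan-converted to
#' Cartesian (labels by nearest neighbour, attenuation bilinearly), and the
#' reference simulator renders the target B-mode frame. Per-record seeds
#' are derived deterministically from `(seed, index)` with a 32-bit
#' multiplicative mix, so datasets are reproducible record by record.
#'
#' @param n Number of records (>= 1).
#' @param seed Integer master seed.
#' @param cfg A [phantom_config()] whose grid matches `geometry`.
#' @param geometry A [fan_geometry()].
#' @param sim_cfg A [sim_config()].
#' @param lut Tissue LUT.
#' @param lowquality Logical; additionally render the degraded image `l`
#'   (for the LSA2H variant).
#' @return A `usgan_dataset`: list of records (each with Cartesian `s`,
#'   `a`, `y`, mask `m`, optionally `l`) plus the generating configuration.
#' @export
make_dataset <- function(n, seed, cfg = phantom_config(),
                         geometry = fan_geometry(n_axial = cfg$n_axial,
                                                 n_lines = cfg$n_lines),
                         sim_cfg = sim_config(), lut = default_lut(),
                         lowquality = FALSE) {
  if (n < 1) stopf("make_dataset: n must be >= 1")
  if (cfg$n_axial != geometry$n_axial || cfg$n_lines != geometry$n_lines)
    stopf("make_dataset: phantom grid and geometry disagree")
  records <- vector("list", n)
  for (i in seq_len(n)) {
    s_pol <- sample_phantom(mix_seed(seed, 2L * i), cfg)
    a_pol <- normalize_attenuation(integral_attenuation(mu_map(s_pol, lut)))
    sc_s <- scan_convert_nearest(unclass(s_pol), geometry)
    sc_a <- scan_convert(unclass(a_pol), geometry)
    y <- render_bmode(s_pol, lut, geometry, sim_cfg, mix_seed(seed, 2L * i + 1L))
    rec <- list(s = sc_s$cartesian, a = sc_a$cartesian * sc_s$mask,
                y = y$values, m = y$mask, seed = mix_seed(seed, 2L * i))
    if (lowquality) {
      l <- render_lowquality(s_pol, lut, geometry, sim_cfg,
                             mix_seed(seed, 2L * i + 1L))
      rec$l <- l$values
    }
    records[[i]] <- rec
  }
  structure(list(records = records, geometry = geometry, lut = lut,
                 phantom_cfg = cfg, sim_cfg = sim_cfg, seed = as.integer(seed),
                 lowquality = isTRUE(lowquality)),
            class = "usgan_dataset")
}

#' @export
length.usgan_dataset <- function(x) length(x$records)

#' @export
print.usgan_dataset <- function(x, ...) {
  d <- dim(x$records[[1]]$s)
  cat(sprintf("<usgan_dataset> %d records, %d x %d Cartesian frames%s, seed %d\n",
              length(x$records), d[1], d[2],
              if (x$lowquality) " (+low-quality)" else "", x$seed))
  invisible(x)
}

#' Write / read a dataset container
#'
#' The container is a single serialized file; identical `(n, seed, config)`
#' produce byte-identical containers.
#'
#' @param ds A `usgan_dataset`.
#' @param path Output path (`.rds`).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   dataset.
#' @export
write_dataset <- function(ds, path) {
  ok <- tryCatch({
    saveRDS(ds, path, compress = "gzip", version = 3)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stopf("dataset write failed: %s", conditionMessage(ok))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stopf("dataset container not found: %s", path)
  ds <- readRDS(path)
  if (!inherits(ds, "usgan_dataset")) stopf("not a usgan dataset: %s", path)
  ds
}

#' Seeded train/validation split
#'
#' @param ds A `usgan_dataset` (or an integer count).
#' @param train_frac Fraction of records assigned to training.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
split_dataset <- function(ds, train_frac = 0.9, seed = 1) {
  n <- if (inherits(ds, "usgan_dataset")) length(ds$records) else as.integer(ds)
  n_train <- max(1L, min(n - 1L, round(train_frac * n)))
  idx <- withr::with_seed(as.integer(seed), sample.int(n))
  list(train = sort(idx[seq_len(n_train)]), val = sort(idx[-seq_len(n_train)]))
}

#' Read / write label maps and images as 8-bit grayscale PNG
#'
#' Label maps store the raw integer code in the 8-bit channel.
#'
#' @param x Matrix (labels or 8-bit intensities).
#' @param path PNG path.
#' @return `read_label_png` an integer matrix; `read_image_png` a numeric
#'   matrix in `[0, 255]`.
#' @export
write_label_png <- function(x, path) {
  png::writePNG(unclass(x) / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_label_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  m <- round(img * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname write_label_png
#' @export
write_image_png <- function(x, path) {
  png::writePNG(pmin(pmax(unclass(x), 0), 255) / 255, path)
  invisible(path)
}

#' @rdname write_label_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 255)
}

#' Write / read a tissue LUT as YAML
#'
#' @param lut A `usgan_tissue_lut`.
#' @param path YAML path.
#' @export
write_lut <- function(lut, path) {
  yaml::write_yaml(lapply(unclass(lut), function(p) p), path)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  structure(yaml::read_yaml(path), class = "usgan_tissue_lut")
}
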
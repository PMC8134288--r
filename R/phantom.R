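#' Tissue label codes used by the procedural phantom
#'
#' The phantom generator uses a fixed small taxonomy: `0` background soft
#' tissue, `1` liver-like hyperechoic inclusion, `2` anechoic cyst/fluid,
#' `3` hypoechoic muscle, `4` bone (strongly attenuating, casts shadows).
#'
#' @return Named integer vector of tissue codes.
#' @export
us_labels <- function() {
  c(background = 0L, liver = 1L, cyst = 2L, muscle = 3L, bone = 4L)
}

#' Configuration for the procedural phantom generator
#'
#' Phantoms are drawn on the beam-aligned (pre-scan-conversion) grid:
#' rows are axial samples along the propagation direction, columns are
#' scanlines ordered by increasing steering angle. Soft-tissue inclusions
#' are random rotated ellipses; bone is drawn as small discs confined to an
#' axial band so that their shadows fall inside the image.
#'
#' @param n_axial,n_lines Grid size (axial samples x scanlines).
#' @param n_liver,n_cyst,n_muscle,n_bone Integer ranges `c(min, max)` for the
#'   number of inclusions of each class.
#' @param r_frac Semi-axis range for soft inclusions, as a fraction of the
#'   grid height.
#' @param bone_r_frac Bone disc radius range, as a fraction of grid height.
#' @param bone_band Axial band (fractions of depth) in which bone centres
#'   are placed; kept shallow so shadows are visible below.
#' @param coverage_band Declared plausible range for the mean fraction of
#'   non-background pixels (checked by the test census, not enforced
#'   per-phantom).
#' @return A list of class `usgan_phantom_config`.
#' @export
phantom_config <- function(n_axial = 64L, n_lines = 64L,
                           n_liver = c(1L, 2L), n_cyst = c(1L, 2L),
                           n_muscle = c(1L, 2L), n_bone = c(1L, 2L),
                           r_frac = c(0.08, 0.22),
                           bone_r_frac = c(0.04, 0.08),
                           bone_band = c(0.12, 0.45),
                           coverage_band = c(0.05, 0.60)) {
  if (n_axial <= 0 || n_lines <= 0)
    stopf("phantom_config: grid dimensions must be positive")
  for (rng in list(n_liver, n_cyst, n_muscle, n_bone))
    if (length(rng) != 2 || any(rng < 0) || rng[2] < rng[1])
      stopf("phantom_config: count ranges must be c(min, max) with 0 <= min <= max")
  if (any(r_frac <= 0) || r_frac[2] < r_frac[1] ||
      any(bone_r_frac <= 0) || bone_r_frac[2] < bone_r_frac[1])
    stopf("phantom_config: size ranges must be positive and non-empty")
  structure(list(n_axial = as.integer(n_axial), n_lines = as.integer(n_lines),
                 n_liver = as.integer(n_liver), n_cyst = as.integer(n_cyst),
                 n_muscle = as.integer(n_muscle), n_bone = as.integer(n_bone),
                 r_frac = r_frac, bone_r_frac = bone_r_frac,
                 bone_band = bone_band, coverage_band = coverage_band),
            class = "usgan_phantom_config")
}

paint_ellipse <- function(grid, label, cr, cc, a, b, theta) {
  H <- nrow(grid); W <- ncol(grid)
  rr <- matrix(seq_len(H), H, W) - cr
  cc_ <- matrix(seq_len(W), H, W, byrow = TRUE) - cc
  u <- rr * cos(theta) + cc_ * sin(theta)
  v <- -rr * sin(theta) + cc_ * cos(theta)
  grid[(u / a)^2 + (v / b)^2 <= 1] <- label
  grid
}

#' Sample a random tissue label map
#'
#' Draws a piecewise-constant anatomy on the beam-aligned grid: background
#' soft tissue with hyperechoic (liver-like), anechoic (cyst), hypoechoic
#' (muscle) elliptical inclusions and one or more small high-attenuation
#' bone discs. All randomness flows from `seed`; identical `(seed, cfg)`
#' yield bit-identical maps.
#'
#' @param seed Integer seed.
#' @param cfg A [phantom_config()].
#' @return A `usgan_label_map`: integer matrix (axial x scanlines) with a
#'   `labels` attribute listing the codes present.
#' @export
sample_phantom <- function(seed, cfg = phantom_config()) {
  if (!inherits(cfg, "usgan_phantom_config"))
    stopf("sample_phantom: cfg must come from phantom_config()")
  H <- cfg$n_axial; W <- cfg$n_lines
  lab <- us_labels()
  grid <- withr::with_seed(as.integer(seed), {
    g <- matrix(lab[["background"]], H, W)
    draw_n <- function(rng) if (rng[2] == rng[1]) rng[1] else
      sample(seq(rng[1], rng[2]), 1)
    soft <- list(liver = cfg$n_liver, cyst = cfg$n_cyst, muscle = cfg$n_muscle)
    for (nm in names(soft)) {
      for (i in seq_len(draw_n(soft[[nm]]))) {
        a <- runif(1, cfg$r_frac[1], cfg$r_frac[2]) * H
        b <- runif(1, cfg$r_frac[1], cfg$r_frac[2]) * H
        cr <- runif(1, 0.15 * H, 0.95 * H)
        cc <- runif(1, 0.1 * W, 0.9 * W)
        g <- paint_ellipse(g, lab[[nm]], cr, cc, a, b, runif(1, 0, pi))
      }
    }
    for (i in seq_len(draw_n(cfg$n_bone))) {
      r <- runif(1, cfg$bone_r_frac[1], cfg$bone_r_frac[2]) * H
      cr <- runif(1, cfg$bone_band[1] * H, cfg$bone_band[2] * H)
      cc <- runif(1, 0.12 * W, 0.88 * W)
      g <- paint_ellipse(g, lab[["bone"]], cr, cc, r, r, 0)
    }
    g
  })
  storage.mode(grid) <- "integer"
  structure(grid, labels = sort(unique(as.integer(grid))),
            class = c("usgan_label_map", class(grid)))
}

#' Default tissue property look-up table
#'
#' Maps each tissue code to acoustic properties: `mu` the attenuation
#' coefficient per axial sample (dimensionless; frequency and cm-per-sample
#' conversion folded in, so the cumulative sum `exp(-sum(mu))` is unitless),
#' `echo_mean`/`echo_std` the scatterer amplitude distribution in `[0, 1]`,
#' and `impedance` the relative acoustic impedance. Values are plausible for
#' abdominal tissue at a desk-scale grid, not calibrated measurements: bone
#' attenuates > 10x background (deep shadows), the cyst is anechoic
#' (`echo_mean = 0`).
#'
#' @return A `usgan_tissue_lut`: named list (by label code) of property lists.
#' @export
default_lut <- function() {
  lut <- list(
    `0` = list(name = "background", mu = 0.004, echo_mean = 0.45,
               echo_std = 0.10, impedance = 1.00),
    `1` = list(name = "liver", mu = 0.006, echo_mean = 0.70,
               echo_std = 0.20, impedance = 1.06),
    `2` = list(name = "cyst", mu = 0.001, echo_mean = 0.00,
               echo_std = 0.00, impedance = 0.80),
    `3` = list(name = "muscle", mu = 0.005, echo_mean = 0.25,
               echo_std = 0.05, impedance = 1.12),
    `4` = list(name = "bone", mu = 0.30, echo_mean = 0.90,
               echo_std = 0.30, impedance = 5.00)
  )
  structure(lut, class = "usgan_tissue_lut")
}

lut_field <- function(lut, field) {
  vapply(lut, function(p) p[[field]], numeric(1))
}

#' Look up one tissue property for every pixel of a label map
#'
#' @param s Integer label matrix.
#' @param lut A tissue LUT ([default_lut()]).
#' @param field Property name, e.g. `"mu"` or `"impedance"`.
#' @return Numeric matrix of the same shape as `s`.
#' @export
lut_lookup <- function(s, lut, field) {
  codes <- as.integer(names(lut))
  vals <- lut_field(lut, field)
  idx <- match(as.integer(s), codes)
  if (anyNA(idx)) {
    bad <- unique(as.integer(s)[is.na(idx)])
    stopf("unknown tissue label(s) not in LUT: %s",
          paste(bad, collapse = ", "))
  }
  matrix(vals[idx], nrow(s), ncol(s))
}
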
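#' Reference simulator configuration
#'
#' Parameters of the simplified convolutional B-mode simulator. The point
#' spread function (PSF) is a Gaussian-windowed axial cosine; it is made
#' spatially variant by evaluating it in `n_bands` depth bands whose widths
#' interpolate linearly between `sigma_ax`/`sigma_lat` endpoints, and
#' blending the banded convolutions with triangular weights.
#'
#' @param ax_period Axial carrier period of the PSF, in samples.
#' @param sigma_ax Axial Gaussian widths (samples) at the shallowest and
#'   deepest band.
#' @param sigma_lat Lateral Gaussian widths (scanlines) at the shallowest
#'   and deepest band.
#' @param n_bands Number of depth bands (default 3).
#' @param tgc_gain Per-sample exponential time-gain-compensation rate;
#'   the default compensates the background attenuation of [default_lut()].
#' @param dynamic_range_db Log-compression dynamic range in dB.
#' @param reflection_gain Scale of the boundary-reflection term derived
#'   from axial impedance contrast.
#' @param attenuation Logical; multiply the RF signal by the unnormalized
#'   integral transmission map (shadowing physics).
#' @param degradation Integer factor for the low-quality renderer: PSF
#'   widths are multiplied by it and the compressed image is block-down-
#'   sampled then nearest-upsampled by it. 1 = no degradation.
#' @return A list of class `usgan_sim_config`.
#' @export
sim_config <- function(ax_period = 6, sigma_ax = c(1.2, 2.2),
                       sigma_lat = c(0.9, 1.8), n_bands = 3L,
                       tgc_gain = 0.004, dynamic_range_db = 45,
                       reflection_gain = 1.5, attenuation = TRUE,
                       degradation = 1L) {
  if (any(sigma_ax <= 0) || any(sigma_lat <= 0))
    stopf("sim_config: PSF widths must be positive")
  if (dynamic_range_db <= 0) stopf("sim_config: dynamic range must be positive")
  structure(list(ax_period = ax_period, sigma_ax = sigma_ax,
                 sigma_lat = sigma_lat, n_bands = as.integer(n_bands),
                 tgc_gain = tgc_gain, dynamic_range_db = dynamic_range_db,
                 reflection_gain = reflection_gain,
                 attenuation = isTRUE(attenuation),
                 degradation = as.integer(degradation)),
            class = "usgan_sim_config")
}

#' Random scatterer amplitude field
#'
#' Per pixel, draws an amplitude from `Normal(echo_mean, echo_std)` of the
#' pixel's tissue, rectified at 0 (amplitudes are non-negative). Anechoic
#' tissue (`echo_mean = echo_std = 0`) yields exact zeros. Deterministic
#' under `seed`.
#'
#' @param s Label map (polar grid).
#' @param lut Tissue LUT.
#' @param seed Integer seed.
#' @return Numeric matrix of scatterer amplitudes.
#' @export
scatterer_field <- function(s, lut, seed) {
  mu <- lut_lookup(s, lut, "echo_mean")
  sdv <- lut_lookup(s, lut, "echo_std")
  withr::with_seed(as.integer(seed), {
    pmax(mu + sdv * matrix(rnorm(length(s)), nrow(s), ncol(s)), 0)
  })
}

# PSF kernel for a given pair of Gaussian widths; unit L2 norm so the
# speckle statistics stay stationary across bands.
psf_kernel <- function(sigma_a, sigma_l, ax_period) {
  ra <- max(3L, ceiling(3 * sigma_a)); rl <- max(2L, ceiling(3 * sigma_l))
  za <- seq(-ra, ra)
  ax <- exp(-za^2 / (2 * sigma_a^2)) * cos(2 * pi * za / ax_period)
  la <- exp(-seq(-rl, rl)^2 / (2 * sigma_l^2))
  k <- outer(ax, la)
  # RF is bandpass: remove the DC component (projected on the Gaussian
  # envelope so the kernel shape is preserved), then normalize energy so
  # speckle statistics are stationary across depth bands
  w <- outer(exp(-za^2 / (2 * sigma_a^2)), la)
  k <- k - sum(k) / sum(w) * w
  k / sqrt(sum(k^2))
}

band_weights <- function(H, n_bands) {
  centers <- (seq_len(n_bands) - 0.5) / n_bands * H
  z <- seq_len(H)
  w <- sapply(seq_len(n_bands), function(b) {
    pmax(0, 1 - abs(z - centers[b]) / (H / n_bands))
  })
  w[1, 1] <- max(w[1, 1], 1e-9)
  sw <- rowSums(w)
  sw[sw == 0] <- 1
  w / sw
}

#' Simulate RF speckle by depth-banded PSF convolution
#'
#' Convolves the scatterer field with the Gaussian-windowed axial cosine
#' PSF, evaluated in depth bands with linearly interpolated widths and
#' blended with triangular row weights (a desk-scale proxy for a
#' continuously varying PSF).
#'
#' @param scatterers Scatterer amplitude matrix (polar).
#' @param cfg A [sim_config()].
#' @param band_scale Internal multiplier on PSF widths (used by the
#'   low-quality renderer).
#' @return RF matrix, same shape.
#' @export
simulate_rf <- function(scatterers, cfg = sim_config(), band_scale = 1) {
  if (!all(is.finite(scatterers))) stopf("simulate_rf: non-finite scatterers")
  H <- nrow(scatterers)
  nb <- cfg$n_bands
  fr <- if (nb == 1) 0.5 else (seq_len(nb) - 1) / (nb - 1)
  w <- band_weights(H, nb)
  out <- matrix(0, H, ncol(scatterers))
  for (b in seq_len(nb)) {
    sa <- (cfg$sigma_ax[1] + fr[b] * diff(cfg$sigma_ax)) * band_scale
    sl <- (cfg$sigma_lat[1] + fr[b] * diff(cfg$sigma_lat)) * band_scale
    k <- psf_kernel(sa, sl, cfg$ax_period)
    # blend by SOURCE depth: each scatterer radiates the PSF of its own
    # band, so an impulse at a band centre reproduces that kernel exactly
    out <- out + conv2_same(scatterers * w[, b], k)
  }
  out
}

# Per-column envelope via the magnitude of the analytic signal, zero-padded
# to twice the column length so the circular Hilbert transform does not wrap
# bright shallow echoes into the deep rows.
envelope <- function(rf) {
  H <- nrow(rf)
  L <- 2L * H
  h <- numeric(L)
  h[c(1, L / 2 + 1)] <- 1
  h[2:(L / 2)] <- 2
  apply(rf, 2, function(col) {
    Mod(fft(fft(c(col, numeric(L - H))) * h, inverse = TRUE) / L)[seq_len(H)]
  })
}

log_compress <- function(env, dr_db) {
  xmax <- quantile(env[env > 0], 0.995, type = 7, names = FALSE)
  if (!length(xmax) || xmax <= 0) return(matrix(0, nrow(env), ncol(env)))
  db <- 20 * log10(pmax(env, xmax * 10^(-dr_db / 20 - 1)) / xmax)
  round(pmin(pmax(255 * (1 + db / dr_db), 0), 255))
}

render_polar <- function(s, lut, cfg, seed, band_scale = 1) {
  sc <- scatterer_field(s, lut, seed)
  rf <- simulate_rf(sc, cfg, band_scale = band_scale)
  if (cfg$reflection_gain > 0) {
    imp <- lut_lookup(s, lut, "impedance")
    dz <- rbind(matrix(0, 1, ncol(imp)), abs(diff(imp)) / (imp[-1, ] + imp[-nrow(imp), ]))
    refl <- conv2_same(dz, matrix(exp(-outer(seq(-2, 2)^2, seq(-2, 2)^2, "+") / 4), 5, 5))
    # reflections arrive on the axial carrier (bandpass like the speckle RF);
    # a baseband bump would bleed long analytic-signal tails into shadows
    carrier <- cos(2 * pi * (seq_len(nrow(refl)) - 1) / cfg$ax_period)
    rf <- rf + cfg$reflection_gain * refl * carrier
  }
  if (cfg$attenuation) {
    a <- integral_attenuation(mu_map(s, lut))
    rf <- rf * unclass(a)
  }
  env <- envelope(rf)
  env <- env * exp(cfg$tgc_gain * (seq_len(nrow(env)) - 1))
  log_compress(env, cfg$dynamic_range_db)
}

#' Render a B-mode image from a label map
#'
#' Full reference pipeline: scatterer draw, depth-banded PSF convolution,
#' boundary reflections from axial impedance contrast, multiplicative
#' shadowing by the unnormalized integral transmission, analytic-signal
#' envelope, exponential time-gain compensation, log compression to 8 bits,
#' convex scan conversion and fan masking.
#'
#' @param s Label map (polar grid).
#' @param lut Tissue LUT.
#' @param g A [fan_geometry()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed for the speckle realization.
#' @param polar Logical; return the pre-scan-conversion polar image
#'   instead of the Cartesian frame (diagnostics).
#' @return A `usgan_bmode` list: `values` (8-bit Cartesian matrix), `mask`,
#'   and `provenance` (seed + config), or the polar matrix if `polar = TRUE`.
#' @export
render_bmode <- function(s, lut, g, cfg = sim_config(), seed = 1,
                         polar = FALSE) {
  img <- render_polar(s, lut, cfg, seed)
  if (polar) return(img)
  sc <- scan_convert(img, g)
  structure(list(values = round(sc$cartesian * sc$mask), mask = sc$mask,
                 provenance = list(seed = as.integer(seed), cfg = cfg)),
            class = "usgan_bmode")
}

#' Render a degraded low-quality B-mode image
#'
#' Same speckle realization and mask as [render_bmode()] but with PSF widths
#' scaled by the degradation factor and the compressed polar image block-
#' downsampled then nearest-upsampled by it. `degradation = 1` reproduces
#' [render_bmode()] exactly.
#'
#' @inheritParams render_bmode
#' @export
render_lowquality <- function(s, lut, g, cfg = sim_config(), seed = 1,
                              polar = FALSE) {
  f <- max(1L, cfg$degradation)
  img <- render_polar(s, lut, cfg, seed, band_scale = f)
  if (f > 1L) {
    H <- nrow(img); W <- ncol(img)
    H2 <- H %/% f; W2 <- W %/% f
    small <- pool_avg(array(img[seq_len(H2 * f), seq_len(W2 * f)],
                            c(H2 * f, W2 * f, 1, 1)), f)[, , 1, 1]
    up <- small[rep(seq_len(H2), each = f), rep(seq_len(W2), each = f)]
    img2 <- img
    img2[seq_len(H2 * f), seq_len(W2 * f)] <- up
    img <- round(img2)
  }
  if (polar) return(img)
  sc <- scan_convert(img, g)
  structure(list(values = round(sc$cartesian * sc$mask), mask = sc$mask,
                 provenance = list(seed = as.integer(seed), cfg = cfg,
                                   degraded = f)),
            class = "usgan_bmode")
}
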
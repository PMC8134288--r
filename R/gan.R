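# Generator and discriminator construction, forward passes and variants.
#
# Networks are stored as plain named lists of parameter arrays plus their
# config; every forward pass builds a fresh autodiff tape from those
# arrays, so networks are ordinary serializable R objects.

#' Generator configuration
#'
#' Describes the image-translation generator: an encoder of stride-2 4x4
#' convolutions, a mirrored decoder of stride-2 4x4 transposed convolutions
#' (even kernel sizes avoid checkerboard artifacts) with U-Net skip
#' connections, and four switchable architectural components: `use_concat`
#' (network inputs, resized per scale, concatenated to every intermediate
#' layer), `use_noise_injection` (per-scale Gaussian noise images added
#' after the skip connection with learned per-channel weights), and
#' `use_texture_decoder` (two extra stride-1 3x3 convolutions per decoder
#' block), `use_attenuation` (integral attenuation map as input).
#'
#' @param inputs Character vector of input planes, in order: `"s"`
#'   (segmentation one-hot), `"a"` (integral attenuation), `"l"`
#'   (low-quality render), `"n"` (input noise plane).
#' @param image_size Spatial size (square), divisible by `2^n_down`.
#' @param base_channels First-scale channel count; deeper scales double,
#'   capped at `max_channels`.
#' @param n_down Number of downsampling blocks (default 4).
#' @param use_concat,use_noise_injection,use_texture_decoder,use_attenuation
#'   The four architectural switches.
#' @param n_labels Number of tissue classes for the one-hot `"s"` planes.
#' @param variant Optional variant name carried for reporting.
#' @return A list of class `usgan_generator_config`.
#' @export
generator_config <- function(inputs = c("s", "a"), image_size = 64L,
                             base_channels = 16L, n_down = 4L,
                             use_concat = TRUE, use_noise_injection = TRUE,
                             use_texture_decoder = TRUE,
                             use_attenuation = TRUE,
                             n_labels = 5L, variant = "SA2H") {
  if (n_down < 1) stopf("generator_config: n_down must be >= 1")
  if (image_size %% 2^n_down != 0)
    stopf("generator_config: image size %d not divisible by 2^%d",
          image_size, n_down)
  if (!all(inputs %in% c("s", "a", "l", "n")))
    stopf("generator_config: unknown input plane(s)")
  if (use_attenuation != ("a" %in% inputs))
    stopf("generator_config: use_attenuation must match presence of 'a' input")
  structure(list(inputs = inputs, image_size = as.integer(image_size),
                 base_channels = as.integer(base_channels),
                 n_down = as.integer(n_down),
                 max_channels = 8L * as.integer(base_channels),
                 use_concat = isTRUE(use_concat),
                 use_noise_injection = isTRUE(use_noise_injection),
                 use_texture_decoder = isTRUE(use_texture_decoder),
                 use_attenuation = isTRUE(use_attenuation),
                 n_labels = as.integer(n_labels), variant = variant),
            class = "usgan_generator_config")
}

input_channels <- function(cfg) {
  ch <- c(s = cfg$n_labels, a = 1L, l = 1L, n = 1L)
  unname(sum(ch[cfg$inputs]))
}

input_kinds <- function(cfg) {
  ch <- c(s = cfg$n_labels, a = 1L, l = 1L, n = 1L)
  rep(cfg$inputs, ch[cfg$inputs])
}

# Channel plan shared by builder and forward pass.
gen_plan <- function(cfg) {
  K <- cfg$n_down
  c0 <- input_channels(cfg)
  che <- pmin(cfg$base_channels * 2^(seq_len(K) - 1), cfg$max_channels)
  enc_in <- integer(K)
  for (i in seq_len(K))
    enc_in[i] <- if (i == 1) c0 else che[i - 1] + if (cfg$use_concat) c0 else 0L
  dec_out <- ifelse(seq_len(K) > 1, che[pmax(seq_len(K) - 1, 1)],
                    cfg$base_channels)
  # h[i] = channels of the running activation entering decoder step i
  dec_in <- integer(K); post <- integer(K)
  h <- che[K]
  for (i in rev(seq_len(K))) {
    dec_in[i] <- h + if (cfg$use_concat) c0 else 0L
    t_ch <- dec_out[i] + if (i > 1) che[i - 1] else 0L
    post[i] <- t_ch                       # channels where noise is injected
    h <- if (cfg$use_texture_decoder) dec_out[i] else t_ch
  }
  list(K = K, c0 = c0, che = che, enc_in = enc_in, dec_in = dec_in,
       dec_out = dec_out, post = post, head_in = h)
}

rinit <- function(dims, sd = 0.02) array(rnorm(prod(dims), 0, sd), dims)

#' Build a generator
#'
#' Instantiates all parameters of the configured generator with Gaussian
#' initialization (sd 0.02); learned noise weights start at 0 so the noise
#' path is initially inactive.
#'
#' @param cfg A [generator_config()].
#' @return A `usgan_generator`: list with `params` (named arrays) and `cfg`.
#' @export
build_generator <- function(cfg) {
  pl <- gen_plan(cfg)
  p <- list()
  for (i in seq_len(pl$K)) {
    p[[sprintf("enc%d.conv.W", i)]] <- rinit(c(4, 4, pl$enc_in[i], pl$che[i]))
    p[[sprintf("enc%d.conv.b", i)]] <- numeric(pl$che[i])
  }
  for (i in rev(seq_len(pl$K))) {
    p[[sprintf("dec%d.tconv.W", i)]] <- rinit(c(4, 4, pl$dec_out[i], pl$dec_in[i]))
    p[[sprintf("dec%d.tconv.b", i)]] <- numeric(pl$dec_out[i])
    if (cfg$use_noise_injection)
      p[[sprintf("dec%d.noise.w", i)]] <- numeric(pl$post[i])
    if (cfg$use_texture_decoder) {
      p[[sprintf("dec%d.tex1.W", i)]] <- rinit(c(3, 3, pl$post[i], pl$dec_out[i]))
      p[[sprintf("dec%d.tex1.b", i)]] <- numeric(pl$dec_out[i])
      p[[sprintf("dec%d.tex2.W", i)]] <- rinit(c(3, 3, pl$dec_out[i], pl$dec_out[i]))
      p[[sprintf("dec%d.tex2.b", i)]] <- numeric(pl$dec_out[i])
    }
  }
  p[["out.conv.W"]] <- rinit(c(3, 3, pl$head_in, 1))
  p[["out.conv.b"]] <- numeric(1)
  structure(list(params = p, cfg = cfg), class = "usgan_generator")
}

#' Number of trainable parameters of a network
#'
#' @param net A `usgan_generator` or `usgan_discriminator`.
#' @return Integer parameter count.
#' @export
n_params <- function(net) sum(vapply(net$params, length, integer(1)))

# Multi-scale constant pyramid of the input stack: nearest-neighbour for
# one-hot segmentation planes (categorical), average pooling otherwise.
input_pyramid <- function(x0, kinds, K) {
  pyr <- vector("list", K)
  for (k in seq_len(K)) {
    f <- 2^k
    s_idx <- which(kinds == "s")
    out <- NULL
    if (length(s_idx)) out <- pool_nearest(x0[, , s_idx, , drop = FALSE], f)
    if (length(s_idx) < length(kinds)) {
      o2 <- pool_avg(x0[, , -s_idx, , drop = FALSE], f)
      out <- if (is.null(out)) o2 else {
        d <- dim(out)
        comb <- array(0, c(d[1], d[2], length(kinds), d[4]))
        comb[, , s_idx, ] <- out
        comb[, , -s_idx, ] <- o2
        comb
      }
    }
    pyr[[k]] <- out
  }
  pyr
}

# Generator forward pass on a tape. `leaves` is the named list of parameter
# leaf nodes; `x0` a plain (H, W, C, N) input array; `zs` a list of noise
# images per decoder block (index i = decoder step, each (Hi, Wi, 1, N)),
# or NULL to draw from the ambient RNG when noise injection is enabled.
gen_forward <- function(tape, leaves, cfg, x0, zs = NULL) {
  pl <- gen_plan(cfg)
  K <- pl$K
  d <- dim(x0)
  kinds <- input_kinds(cfg)
  pyr <- if (cfg$use_concat) input_pyramid(x0, kinds, K) else NULL
  L <- function(nm) leaves[[nm]]
  x0n <- ag_leaf(tape, x0)
  h <- x0n
  enc <- vector("list", K)
  for (i in seq_len(K)) {
    inp <- if (i > 1 && cfg$use_concat)
      ag_concat(tape, list(h, ag_leaf(tape, pyr[[i - 1]]))) else h
    ci <- ag_conv(tape, inp, L(sprintf("enc%d.conv.W", i)),
                  L(sprintf("enc%d.conv.b", i)), stride = 2L, pad = 1L)
    enc[[i]] <- ag_instnorm(tape, ag_lrelu(tape, ci, 0.2))
    h <- enc[[i]]
  }
  for (i in rev(seq_len(K))) {
    inp <- if (cfg$use_concat)
      ag_concat(tape, list(h, ag_leaf(tape, pyr[[i]]))) else h
    t <- ag_tconv(tape, inp, L(sprintf("dec%d.tconv.W", i)),
                  L(sprintf("dec%d.tconv.b", i)), stride = 2L, pad = 1L)
    t <- ag_instnorm(tape, ag_relu(tape, t))
    if (i > 1) t <- ag_concat(tape, list(t, enc[[i - 1]]))
    if (cfg$use_noise_injection) {
      di <- dim(t$val)
      z <- if (!is.null(zs)) zs[[i]] else
        array(rnorm(di[1] * di[2] * di[4]), c(di[1], di[2], 1, di[4]))
      t <- ag_add_noise(tape, t, L(sprintf("dec%d.noise.w", i)), z)
    }
    if (cfg$use_texture_decoder) {
      t <- ag_instnorm(tape, ag_relu(tape, ag_conv(
        tape, t, L(sprintf("dec%d.tex1.W", i)), L(sprintf("dec%d.tex1.b", i)),
        stride = 1L, pad = 1L)))
      t <- ag_instnorm(tape, ag_relu(tape, ag_conv(
        tape, t, L(sprintf("dec%d.tex2.W", i)), L(sprintf("dec%d.tex2.b", i)),
        stride = 1L, pad = 1L)))
    }
    h <- t
  }
  ag_tanh(tape, ag_conv(tape, h, L("out.conv.W"), L("out.conv.b"),
                        stride = 1L, pad = 1L))
}

make_leaves <- function(tape, params) lapply(params, ag_leaf, tape = tape)

#' Run the generator on an input batch (inference)
#'
#' @param gen A `usgan_generator`.
#' @param x0 Input array `(H, W, C, N)` matching the config's input planes
#'   (see [make_input_stack()]).
#' @param zs Optional list of per-scale noise images; `NULL` draws fresh
#'   noise from the current RNG state when noise injection is enabled.
#' @return Array `(H, W, 1, N)` in `[-1, 1]`.
#' @export
generator_predict <- function(gen, x0, zs = NULL) {
  tape <- new_tape()
  leaves <- make_leaves(tape, gen$params)
  gen_forward(tape, leaves, gen$cfg, x0, zs)$val
}

#' Discriminator configuration
#'
#' PatchGAN discriminator: `n_layers` stride-2 4x4 convolutions followed by
#' a stride-1 4x4 convolution to a single-channel spatial logit map, so
#' each logit judges a local receptive field rather than the whole image.
#'
#' @param in_channels Channels of the (image, conditioning) stack.
#' @param base_channels First-layer channel count.
#' @param n_layers Number of stride-2 layers (default 3).
#' @param norm Apply instance normalization after the activations of layers
#'   past the first (default). Note normalization couples logits through
#'   the per-image statistics, so patch locality is exact only when it is
#'   disabled.
#' @return A list of class `usgan_discriminator_config`.
#' @export
discriminator_config <- function(in_channels, base_channels = 16L,
                                 n_layers = 3L, norm = TRUE) {
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 n_layers = as.integer(n_layers), norm = isTRUE(norm)),
            class = "usgan_discriminator_config")
}

#' Build a patchGAN discriminator
#'
#' @param cfg A [discriminator_config()].
#' @return A `usgan_discriminator`: list with `params` and `cfg`.
#' @export
build_discriminator <- function(cfg) {
  p <- list()
  cin <- cfg$in_channels
  for (i in seq_len(cfg$n_layers)) {
    cout <- min(cfg$base_channels * 2^(i - 1), 8L * cfg$base_channels)
    p[[sprintf("d%d.conv.W", i)]] <- rinit(c(4, 4, cin, cout))
    p[[sprintf("d%d.conv.b", i)]] <- numeric(cout)
    cin <- cout
  }
  p[["dout.conv.W"]] <- rinit(c(4, 4, cin, 1))
  p[["dout.conv.b"]] <- numeric(1)
  structure(list(params = p, cfg = cfg), class = "usgan_discriminator")
}

# Discriminator forward on a tape: x is an image/conditioning stack node.
disc_forward <- function(tape, leaves, cfg, x) {
  h <- x
  for (i in seq_len(cfg$n_layers)) {
    h <- ag_conv(tape, h, leaves[[sprintf("d%d.conv.W", i)]],
                 leaves[[sprintf("d%d.conv.b", i)]], stride = 2L, pad = 1L)
    h <- ag_lrelu(tape, h, 0.2)
    if (i > 1 && cfg$norm) h <- ag_instnorm(tape, h)
  }
  ag_conv(tape, h, leaves[["dout.conv.W"]], leaves[["dout.conv.b"]],
          stride = 1L, pad = 1L)
}

#' Run the discriminator on an input stack (inference)
#'
#' @param disc A `usgan_discriminator`.
#' @param x Array `(H, W, C, N)`.
#' @return Logit map array `(Hd, Wd, 1, N)` with `Hd < H`.
#' @export
discriminator_predict <- function(disc, x) {
  tape <- new_tape()
  leaves <- make_leaves(tape, disc$params)
  disc_forward(tape, leaves, disc$cfg, ag_leaf(tape, x))$val
}

#' Analytic receptive field of the encoder bottleneck
#'
#' Composes kernel sizes and strides of the `n_down` stride-2 4x4 encoder
#' convolutions: `rf <- rf + (k - 1) * jump`, `jump <- jump * stride`. A
#' deliberately small receptive field preserves spatial locality; the
#' attenuation input carries the global shadow information instead.
#'
#' @param cfg A [generator_config()], or a list of `c(kernel, stride)`
#'   pairs for arbitrary stacks.
#' @return Integer receptive-field side length (pixels).
#' @export
receptive_field <- function(cfg) {
  layers <- if (inherits(cfg, "usgan_generator_config"))
    rep(list(c(4L, 2L)), cfg$n_down) else cfg
  rf <- 1L; jump <- 1L
  for (ks in layers) {
    rf <- rf + (ks[1] - 1L) * jump
    jump <- jump * ks[2]
  }
  rf
}

#' Construct a named model variant
#'
#' Returns the generator configuration and input specification of the
#' proposed model (`SA2H`), its four single-component ablations
#' (`SA2H-att`, `SA2H-concat`, `SA2H-conv`, `SA2H-noise`), the
#' low-quality-input silver standard `LSA2H` and the noise-input baseline
#' `NSA2H`. `LSA2H`/`NSA2H` follow the earlier translation architecture:
#' none of the four components, double base width (~4x the parameters).
#'
#' @param name Variant name.
#' @param image_size,base_channels,n_down,n_labels Scale parameters
#'   forwarded to [generator_config()]; `LSA2H`/`NSA2H` double
#'   `base_channels`.
#' @return List with `cfg` (generator config) and `inputs`.
#' @export
make_variant <- function(name, image_size = 64L, base_channels = 16L,
                         n_down = 4L, n_labels = 5L) {
  gc <- function(...) generator_config(image_size = image_size,
                                       base_channels = base_channels,
                                       n_down = n_down, n_labels = n_labels,
                                       variant = name, ...)
  cfg <- switch(
    name,
    "SA2H" = gc(inputs = c("s", "a")),
    "SA2H-att" = gc(inputs = "s", use_attenuation = FALSE),
    "SA2H-concat" = gc(inputs = c("s", "a"), use_concat = FALSE),
    "SA2H-conv" = gc(inputs = c("s", "a"), use_texture_decoder = FALSE),
    "SA2H-noise" = gc(inputs = c("s", "a", "n"), use_noise_injection = FALSE),
    "NSA2H" = generator_config(inputs = c("n", "s", "a"),
                               image_size = image_size,
                               base_channels = 2L * base_channels,
                               n_down = n_down, n_labels = n_labels,
                               use_concat = FALSE,
                               use_noise_injection = FALSE,
                               use_texture_decoder = FALSE, variant = name),
    "LSA2H" = generator_config(inputs = c("l", "s", "a"),
                               image_size = image_size,
                               base_channels = 2L * base_channels,
                               n_down = n_down, n_labels = n_labels,
                               use_concat = FALSE,
                               use_noise_injection = FALSE,
                               use_texture_decoder = FALSE, variant = name),
    stopf("unknown variant '%s'; choose one of %s", name,
          "SA2H, SA2H-att, SA2H-concat, SA2H-conv, SA2H-noise, NSA2H, LSA2H")
  )
  list(cfg = cfg, inputs = cfg$inputs)
}

#' Assemble the generator input stack for one record
#'
#' Builds the `(H, W, C)` channel stack the configured variant expects:
#' one-hot segmentation planes, attenuation map in `[0, 1]`, low-quality
#' image scaled to `[0, 1]`, and/or a standard-normal noise plane (drawn
#' from the current RNG state unless supplied).
#'
#' @param record List with fields `s`, `a`, and optionally `l` (Cartesian).
#' @param cfg A [generator_config()].
#' @param noise_plane Optional precomputed noise plane matrix.
#' @return Array `(H, W, C)`.
#' @export
make_input_stack <- function(record, cfg, noise_plane = NULL) {
  planes <- list()
  for (p in cfg$inputs) {
    planes[[p]] <- switch(
      p,
      s = one_hot(record$s, seq_len(cfg$n_labels) - 1L),
      a = array(unclass(record$a), c(dim(record$a), 1)),
      l = array(record$l / 255, c(dim(record$l), 1)),
      n = {
        z <- noise_plane %||% matrix(rnorm(length(record$s)), nrow(record$s))
        array(z, c(dim(z), 1))
      })
  }
  d1 <- dim(planes[[1]])
  array(unlist(planes, use.names = FALSE),
        c(d1[1], d1[2], sum(vapply(planes, function(x) dim(x)[3], numeric(1)))))
}
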
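test_that("generator output has the input spatial shape, one channel, tanh range", {
  cfg <- generator_config(inputs = c("s", "a"), image_size = 64,
                          base_channels = 4, n_down = 4, n_labels = 5)
  gen <- build_generator(cfg)
  x0 <- array(runif(64 * 64 * 6 * 2), c(64, 64, 6, 2))
  set.seed(1)
  out <- generator_predict(gen, x0)
  expect_equal(dim(out), c(64L, 64L, 1L, 2L))
  expect_true(all(out >= -1 & out <= 1))
  expect_error(generator_config(image_size = 60, n_down = 4), "divisible")
})

test_that("forward passes are deterministic without noise injection", {
  cfg <- generator_config(inputs = c("s", "a"), image_size = 32,
                          base_channels = 4, n_down = 3,
                          use_noise_injection = FALSE, n_labels = 2)
  gen <- build_generator(cfg)
  x0 <- array(runif(32 * 32 * 3), c(32, 32, 3, 1))
  expect_identical(generator_predict(gen, x0), generator_predict(gen, x0))
})

test_that("noise path isolation: seeds change outputs only through nonzero weights", {
  vs <- make_variant("SA2H", image_size = 32, base_channels = 4, n_down = 2)
  gen <- build_generator(vs$cfg)
  x0 <- array(runif(32 * 32 * 6), c(32, 32, 6, 1))
  # all learned noise weights are initialized to 0: seeds are inert
  set.seed(10); o1 <- generator_predict(gen, x0)
  set.seed(20); o2 <- generator_predict(gen, x0)
  expect_identical(o1, o2)
  gen2 <- gen
  for (nm in grep("noise\\.w", names(gen2$params), value = TRUE))
    gen2$params[[nm]][] <- 0.5
  set.seed(10); o3 <- generator_predict(gen2, x0)
  set.seed(20); o4 <- generator_predict(gen2, x0)
  expect_false(identical(o3, o4))
})

test_that("discriminator emits a strictly smaller conditional logit map", {
  dcfg <- discriminator_config(4L, base_channels = 4L, n_layers = 3L)
  disc <- build_discriminator(dcfg)
  x <- array(runif(64 * 64 * 4), c(64, 64, 4, 1))
  lg <- discriminator_predict(disc, x)
  expect_lt(dim(lg)[1], 64)
  expect_lt(dim(lg)[2], 64)
  expect_equal(dim(lg)[3], 1L)
  # conditioning sensitivity: changing s channels moves the logits
  x2 <- x
  x2[, , 2, ] <- matrix(runif(64 * 64), 64, 64)
  expect_false(identical(discriminator_predict(disc, x2), lg))
})

test_that("patch logits are local: far-away occlusion leaves a logit unchanged", {
  # normalization off: per-image statistics would couple logits globally
  dcfg <- discriminator_config(2L, base_channels = 4L, n_layers = 3L,
                               norm = FALSE)
  disc <- build_discriminator(dcfg)
  set.seed(6)
  x <- array(runif(64 * 64 * 2), c(64, 64, 2, 1))
  lg <- discriminator_predict(disc, x)
  # receptive field of each logit: 3 stride-2 4x4 convs + 4x4 stride-1 head
  rf <- receptive_field(c(rep(list(c(4L, 2L)), 3), list(c(4L, 1L))))
  expect_lt(rf, 64)
  x2 <- x
  x2[1:8, 1:8, , ] <- 0   # occlusion far from the bottom-right logit
  lg2 <- discriminator_predict(disc, x2)
  d <- dim(lg)
  expect_equal(lg2[d[1], d[2], 1, 1], lg[d[1], d[2], 1, 1])
  expect_false(identical(lg2[1, 1, 1, 1], lg[1, 1, 1, 1]))
})

test_that("analytic receptive field matches composition rules and gradient support", {
  expect_equal(receptive_field(list(c(3L, 1L))), 3L)
  expect_equal(receptive_field(list(c(3L, 1L), c(3L, 1L))), 5L)
  expect_equal(receptive_field(generator_config(image_size = 64, n_down = 4)), 46L)
  # empirical oracle: gradient support of one bottleneck unit of a
  # 2-layer stride-2 stack (normalization off, which would couple globally)
  set.seed(2)
  W1 <- array(rnorm(4 * 4 * 1 * 3, 0, .1), c(4, 4, 1, 3))
  W2 <- array(rnorm(4 * 4 * 3 * 4, 0, .1), c(4, 4, 3, 4))
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  tp <- usgan:::new_tape()
  xl <- usgan:::ag_leaf(tp, x)
  l1 <- usgan:::ag_lrelu(tp, usgan:::ag_conv(tp, xl, usgan:::ag_leaf(tp, W1),
                                             usgan:::ag_leaf(tp, numeric(3)), 2L, 1L))
  l2 <- usgan:::ag_conv(tp, l1, usgan:::ag_leaf(tp, W2),
                        usgan:::ag_leaf(tp, numeric(4)), 2L, 1L)
  sel <- array(0, dim(l2$val)); sel[8, 8, 1, 1] <- 1
  loss <- usgan:::ag_l1_const(tp, usgan:::ag_mul_const(tp, l2, sel),
                              array(0, dim(sel)))
  usgan:::ag_backward(tp, loss)
  gx <- abs(xl$grad[, , 1, 1])
  span <- c(diff(range(which(rowSums(gx) > 0))) + 1,
            diff(range(which(colSums(gx) > 0))) + 1)
  expect_equal(span, rep(receptive_field(rep(list(c(4L, 2L)), 2)), 2))
})

test_that("make_variant reproduces the published input/flag combinations", {
  v <- make_variant("SA2H")
  expect_setequal(v$inputs, c("s", "a"))
  expect_true(v$cfg$use_concat && v$cfg$use_noise_injection &&
                v$cfg$use_texture_decoder && v$cfg$use_attenuation)
  v <- make_variant("SA2H-att")
  expect_identical(v$inputs, "s")
  expect_false(v$cfg$use_attenuation)
  v <- make_variant("NSA2H")
  expect_setequal(v$inputs, c("n", "s", "a"))
  expect_false(v$cfg$use_noise_injection)
  v <- make_variant("LSA2H")
  expect_true("l" %in% v$inputs)
  expect_error(make_variant("bogus"), "unknown variant")
})

test_that("toggling one flag changes exactly the corresponding subgraph", {
  base <- build_generator(make_variant("SA2H", image_size = 32,
                                       base_channels = 4, n_down = 2)$cfg)
  nms <- names(base$params)
  # noise ablation removes exactly the learned noise weights
  no_noise <- build_generator(make_variant("SA2H-noise", image_size = 32,
                                           base_channels = 4, n_down = 2)$cfg)
  removed <- setdiff(nms, names(no_noise$params))
  expect_true(all(grepl("noise\\.w$", removed)))
  expect_gte(length(removed), 1)
  # texture ablation removes exactly the stride-1 decoder convolutions
  no_tex <- build_generator(make_variant("SA2H-conv", image_size = 32,
                                         base_channels = 4, n_down = 2)$cfg)
  removed <- setdiff(nms, names(no_tex$params))
  expect_true(all(grepl("tex[12]\\.[Wb]$", removed)))
  # concat ablation keeps the same parameter names, shrinking only the
  # input-channel extent of convolution kernels past the first layer
  no_cat <- build_generator(make_variant("SA2H-concat", image_size = 32,
                                         base_channels = 4, n_down = 2)$cfg)
  expect_setequal(nms, names(no_cat$params))
  for (nm in nms) {
    if (grepl("^enc1\\.|noise\\.w$|\\.b$", nm)) {
      expect_equal(dim(base$params[[nm]]), dim(no_cat$params[[nm]]))
      expect_equal(length(base$params[[nm]]), length(no_cat$params[[nm]]))
    }
  }
  # parameter-count ordering: the larger translation baselines ~4x wider
  expect_gt(n_params(build_generator(make_variant("NSA2H", image_size = 32,
                                                  base_channels = 4,
                                                  n_down = 2)$cfg)),
            n_params(base))
})

test_that("input stacks carry the declared planes", {
  ds <- small_dataset()
  rec <- ds$records[[1]]
  cfg <- make_variant("SA2H", image_size = 32)$cfg
  x <- make_input_stack(rec, cfg)
  expect_equal(dim(x)[3], 6L)        # 5 one-hot labels + attenuation
  expect_true(all(x[, , 1:5] %in% c(0, 1)))
  expect_true(all(x[, , 6] >= 0 & x[, , 6] <= 1))
  expect_equal(apply(x[, , 1:5], c(1, 2), sum), matrix(1, nrow(rec$s), ncol(rec$s)),
               ignore_attr = TRUE)
})
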
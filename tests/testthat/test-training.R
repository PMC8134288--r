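test_that("fidelity loss matches the brute-force masked elementwise oracle", {
  set.seed(1)
  y <- matrix(runif(64, -1, 1), 8, 8)
  expect_equal(fidelity_loss(y, y, matrix(1, 8, 8)), 0)
  expect_equal(fidelity_loss(matrix(0, 8, 8), matrix(0.3, 8, 8),
                             matrix(1, 8, 8)), 0.3, tolerance = 1e-12)
  yh <- matrix(runif(64, -1, 1), 8, 8)
  m <- matrix(rbinom(64, 1, 0.5), 8, 8)
  acc <- 0
  for (k in seq_along(y)) acc <- acc + abs(y[k] - m[k] * yh[k])
  expect_equal(fidelity_loss(y, yh, m), acc / 64, tolerance = 1e-12)
  expect_error(fidelity_loss(y, matrix(0, 2, 2), m), "shape")
})

test_that("adversarial losses: uncertainty, perfect-discriminator limit, oracle", {
  z <- array(0, c(4, 4, 1, 2))
  gl <- gan_losses(z, z)
  expect_equal(gl$discriminator, log(2), tolerance = 1e-12)
  expect_equal(gl$generator_adv, log(2), tolerance = 1e-12)
  # perfect discriminator: real -> +30, fake -> -30 (clamped logits)
  gp <- gan_losses(z + 30, z - 30)
  expect_lt(gp$discriminator, 1e-10)
  # brute-force per-pixel cross-entropy
  set.seed(2)
  lr <- array(rnorm(32), c(4, 4, 1, 2))
  lf <- array(rnorm(32), c(4, 4, 1, 2))
  sp <- function(t) log1p(exp(-abs(t))) + pmax(t, 0)
  d_oracle <- 0.5 * (mean(sp(-lr)) + mean(sp(lf)))
  expect_equal(gan_losses(lr, lf)$discriminator, d_oracle, tolerance = 1e-10)
  expect_equal(gan_losses(lr, lf)$generator_adv, mean(sp(-lf)), tolerance = 1e-10)
  expect_error(gan_losses(lr * NA, lf), "non-finite")
})

test_that("the total generator objective decomposes exactly as adv + lambda * L1", {
  set.seed(5)
  vs <- make_variant("SA2H", image_size = 16, base_channels = 2, n_down = 2)
  gen <- build_generator(vs$cfg)
  dcfg <- discriminator_config(7L, base_channels = 2L, n_layers = 2L)
  disc <- build_discriminator(dcfg)
  x0 <- array(runif(16 * 16 * 6), c(16, 16, 6, 1))
  y <- array(runif(256, -1, 1), c(16, 16, 1, 1))
  lambda <- 100
  tp <- usgan:::new_tape()
  lg <- usgan:::make_leaves(tp, gen$params)
  ld <- usgan:::make_leaves(tp, disc$params)
  fake <- usgan:::gen_forward(tp, lg, vs$cfg, x0)
  dlog <- usgan:::disc_forward(tp, ld, dcfg,
                               usgan:::ag_concat(tp, list(fake, usgan:::ag_leaf(tp, x0))))
  adv <- usgan:::ag_bce_mean(tp, dlog, TRUE)
  l1 <- usgan:::ag_l1_const(tp, fake, y)
  total <- usgan:::ag_axpby(tp, 1, adv, lambda, l1)
  expect_identical(total$val, adv$val + lambda * l1$val)
})

test_that("gradients of the full masked objective vanish outside the fan mask", {
  set.seed(3)
  m <- matrix(0, 16, 16)
  m[4:13, 3:14] <- 1
  m4 <- array(m, c(16, 16, 1, 1))
  y <- array(runif(256, -1, 1), c(16, 16, 1, 1)) * m4
  dcfg <- discriminator_config(1L, base_channels = 2L, n_layers = 2L)
  disc <- build_discriminator(dcfg)
  x <- array(runif(256, -1, 1), c(16, 16, 1, 1))   # stand-in generator output
  tp <- usgan:::new_tape()
  xl <- usgan:::ag_leaf(tp, x)
  masked <- usgan:::ag_mul_const(tp, xl, m4)
  lv <- usgan:::make_leaves(tp, disc$params)
  lg <- usgan:::disc_forward(tp, lv, dcfg, masked)
  loss <- usgan:::ag_axpby(tp, 1, usgan:::ag_bce_mean(tp, lg, TRUE),
                           100, usgan:::ag_l1_const(tp, masked, y))
  usgan:::ag_backward(tp, loss)
  g <- xl$grad[, , 1, 1]
  expect_true(all(g[m == 0] == 0))
  expect_gt(max(abs(g[m == 1])), 0)
})

test_that("zero steps returns the seeded initialization unchanged", {
  ds <- small_dataset()
  tc <- train_config(steps = 0, lambda_fidelity = 0, val_every = 10,
                     base_channels = 4, n_down = 2, disc_base = 4, seed = 9)
  fit <- train_gan(ds, "SA2H", tc)
  expect_equal(nrow(fit$history), 0)
  # identical to an independently built generator under the same seed path
  fit2 <- train_gan(ds, "SA2H", tc)
  expect_identical(fit$generator$params, fit2$generator$params)
  expect_identical(fit$discriminator$params, fit2$discriminator$params)
})

test_that("training is deterministic: same seed and config give identical histories", {
  ds <- small_dataset()
  tc <- train_config(steps = 6, batch_size = 2, val_every = 3,
                     base_channels = 4, n_down = 2, disc_base = 4, seed = 7)
  f1 <- train_gan(ds, "SA2H", tc)
  f2 <- train_gan(ds, "SA2H", tc)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$validation, f2$validation)
  expect_identical(f1$generator$params, f2$generator$params)
})

test_that("the data split is seeded, disjoint and configurable", {
  sp1 <- split_dataset(100, 0.9, seed = 1)
  sp2 <- split_dataset(100, 0.9, seed = 1)
  sp3 <- split_dataset(100, 0.9, seed = 2)
  expect_identical(sp1, sp2)
  expect_false(identical(sp1, sp3))
  expect_length(sp1$train, 90)
  expect_length(intersect(sp1$train, sp1$val), 0)
  expect_setequal(c(sp1$train, sp1$val), 1:100)
})

test_that("variants missing their input modality are rejected", {
  ds <- small_dataset()   # generated without low-quality frames
  tc <- train_config(steps = 1, base_channels = 4, n_down = 2)
  expect_error(train_gan(ds, "LSA2H", tc), "low-quality")
})

test_that("tidy/glance/autoplot accessors work on fits", {
  ds <- small_dataset()
  tc <- train_config(steps = 3, batch_size = 2, val_every = 3,
                     base_channels = 4, n_down = 2, disc_base = 4, seed = 2)
  fit <- train_gan(ds, "SA2H", tc)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("step", "loss_d", "loss_g_adv", "loss_g_l1"))
  g <- glance(fit)
  expect_equal(g$steps, 3)
  expect_gt(g$n_params_g, 0)
  expect_s3_class(autoplot(fit), "ggplot")
  preds <- predict(fit, ds)
  expect_length(preds, length(fit$split$val))
  expect_true(all(preds[[1]] >= 0 & preds[[1]] <= 255))
})

test_that("a single-variant ablation emits the expected table", {
  ds <- small_dataset()
  tc <- train_config(steps = 3, batch_size = 2, val_every = 5,
                     base_channels = 4, n_down = 2, disc_base = 4, seed = 3)
  ab <- run_ablation(ds, "SA2H", tc)
  expect_equal(nrow(ab$table), 1)
  expect_true(all(c("psnr_mean", "mae_mean", "pchi2_mean", "fid",
                    "n_params") %in% names(ab$table)))
  expect_gt(ab$table$n_params, 0)
  expect_s3_class(autoplot(ab, baseline = "SA2H"), "ggplot")
  expect_s3_class(tidy(ab), "tbl_df")
})

test_that("injecting identical prediction and target sets gives the perfect-model row", {
  ds <- small_dataset()
  targets <- lapply(1:4, function(i) ds$records[[i]]$y)
  rp <- metric_report(targets, targets, ds$records[[1]]$m)
  expect_true(all(rp$per_image$psnr == Inf))
  expect_true(all(rp$per_image$mae == 0))
  expect_true(all(rp$per_image$pchi2 == 0))
  expect_lt(abs(rp$fid), 1e-6)
})
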
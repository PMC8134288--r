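# Masked adversarial + L1 objective and the training loop.

#' Training configuration
#'
#' Optimizer and loop hyperparameters. The loss weighting, Adam settings
#' and batch size default to the reference protocol (lambda = 100, lr
#' 2e-4, beta1 0.5, beta2 0.999, batch 4); image/crop size and network
#' width default to desk scale (64 x 64, base 16, 3 downsampling blocks)
#' so training runs on one CPU.
#'
#' @param lambda_fidelity Weight of the masked L1 term (lambda).
#' @param lr,beta1,beta2 Adam settings.
#' @param batch_size Images per step.
#' @param crop_size On-the-fly crop side; `NULL` trains on full frames.
#'   Crops are sampled uniformly among positions with >= 25% fan coverage.
#' @param steps Number of alternating D/G update steps.
#' @param val_every Validation interval (masked L1 on full held-out frames).
#' @param train_frac Seeded train fraction of the dataset.
#' @param seed Master seed for split, initialization, crops and noise.
#' @param base_channels,n_down Generator scale (see [generator_config()]).
#' @param disc_base,disc_layers Discriminator scale.
#' @param non_saturating Use the non-saturating generator loss
#'   (`-log D(fake)`); `FALSE` gives the saturating form `log(1 - D(fake))`.
#' @return A list of class `usgan_train_config`.
#' @export
train_config <- function(lambda_fidelity = 100, lr = 2e-4, beta1 = 0.5,
                         beta2 = 0.999, batch_size = 4L, crop_size = NULL,
                         steps = 500L, val_every = 100L, train_frac = 0.9,
                         seed = 1L, base_channels = 16L, n_down = 3L,
                         disc_base = 16L, disc_layers = 3L,
                         non_saturating = TRUE) {
  if (lambda_fidelity < 0) stopf("train_config: lambda must be >= 0")
  if (batch_size < 1) stopf("train_config: batch_size must be >= 1")
  structure(list(lambda_fidelity = lambda_fidelity, lr = lr, beta1 = beta1,
                 beta2 = beta2, batch_size = as.integer(batch_size),
                 crop_size = if (is.null(crop_size)) NULL else as.integer(crop_size),
                 steps = as.integer(steps), val_every = as.integer(val_every),
                 train_frac = train_frac, seed = as.integer(seed),
                 base_channels = as.integer(base_channels),
                 n_down = as.integer(n_down), disc_base = as.integer(disc_base),
                 disc_layers = as.integer(disc_layers),
                 non_saturating = isTRUE(non_saturating)),
            class = "usgan_train_config")
}

#' Masked L1 fidelity loss
#'
#' Mean absolute difference between the target and the mask-multiplied
#' generator output, averaged over all pixels (and batch).
#'
#' @param y Target array/matrix.
#' @param y_hat Generator output, same shape.
#' @param m Binary mask, same spatial shape.
#' @return Scalar loss.
#' @export
fidelity_loss <- function(y, y_hat, m) {
  if (!all(dim(y) == dim(y_hat))) stopf("fidelity_loss: shape mismatch")
  mm <- if (length(dim(y)) > 2 && length(dim(m)) == 2) array(m, dim(y)) else m
  if (!all(dim(mm) == dim(y))) stopf("fidelity_loss: mask shape mismatch")
  mean(abs(y - mm * y_hat))
}

softplus <- function(t) ifelse(t > 30, t, log1p(exp(pmin(t, 30))))

#' Adversarial loss terms from patch logit maps
#'
#' Binary cross-entropy in logit space, averaged over the spatial logit map
#' and batch. The discriminator term pushes real patches to 1 and fake
#' patches to 0 (mean of the two halves); the generator term is the
#' non-saturating counterpart pushing fake patches to 1.
#'
#' @param logit_real,logit_fake Logit maps (any shape).
#' @param non_saturating Generator term form (see [train_config()]).
#' @return List with `discriminator` and `generator_adv` scalars.
#' @export
gan_losses <- function(logit_real, logit_fake, non_saturating = TRUE) {
  if (!all(is.finite(logit_real)) || !all(is.finite(logit_fake)))
    stopf("gan_losses: non-finite logits")
  d <- 0.5 * (mean(softplus(-logit_real)) + mean(softplus(logit_fake)))
  g <- if (non_saturating) mean(softplus(-logit_fake))
  else -mean(softplus(logit_fake))
  list(discriminator = d, generator_adv = g)
}

# ---- Adam -------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(st, params, grads, lr, b1, b2, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    mh <- st$m[[nm]] / (1 - b1^st$t)
    vh <- st$v[[nm]] / (1 - b2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(state = st, params = params)
}

collect_grads <- function(leaves) {
  out <- lapply(leaves, function(l) l$grad)
  out[!vapply(out, is.null, logical(1))]
}

# ---- data plumbing ----------------------------------------------------

# Conditioning planes for the discriminator: the generator's deterministic
# inputs (s, a, l) without pure noise planes.
cond_inputs <- function(cfg) setdiff(cfg$inputs, "n")

prep_record <- function(rec, gcfg) {
  x_det <- make_input_stack(rec, within_cfg_inputs(gcfg, cond_inputs(gcfg)))
  ym <- (rec$y / 127.5 - 1) * rec$m
  list(x = x_det, y = array(ym, c(dim(ym), 1)), m = rec$m)
}

# A config clone restricted to a subset of input planes (for stack
# assembly only).
within_cfg_inputs <- function(cfg, inputs) {
  cfg$inputs <- inputs
  cfg$use_attenuation <- "a" %in% inputs
  cfg
}

# Sample a crop origin with >= 25% fan coverage (up to 20 attempts, then
# the best seen).
sample_crop <- function(m, crop) {
  H <- nrow(m); W <- ncol(m)
  if (crop >= H && crop >= W) return(c(1L, 1L))
  best <- c(1L, 1L); best_cov <- -1
  for (i in seq_len(20)) {
    r <- sample.int(H - crop + 1L, 1); c <- sample.int(W - crop + 1L, 1)
    cov <- mean(m[r:(r + crop - 1L), c:(c + crop - 1L)])
    if (cov >= 0.25) return(c(r, c))
    if (cov > best_cov) { best <- c(r, c); best_cov <- cov }
  }
  best
}

crop_arr <- function(x, at, crop) {
  idx_r <- at[1]:(at[1] + crop - 1L); idx_c <- at[2]:(at[2] + crop - 1L)
  if (length(dim(x)) == 2) x[idx_r, idx_c]
  else x[idx_r, idx_c, , drop = FALSE]
}

# Assemble a (H, W, C, N) input batch for the generator, drawing noise
# planes from the ambient RNG where the variant requires them.
assemble_inputs <- function(preps, gcfg) {
  xs <- lapply(preps, function(pr) {
    x <- pr$x
    if ("n" %in% gcfg$inputs) {
      # noise plane is inserted at its declared position in cfg$inputs
      planes <- list()
      kinds <- input_kinds(within_cfg_inputs(gcfg, cond_inputs(gcfg)))
      at <- 0L
      for (p in gcfg$inputs) {
        if (p == "n") {
          planes[[length(planes) + 1L]] <-
            array(rnorm(nrow(pr$m) * ncol(pr$m)), c(dim(pr$m), 1))
        } else {
          ch <- sum(kinds == p)
          planes[[length(planes) + 1L]] <- x[, , at + seq_len(ch), drop = FALSE]
          at <- at + ch
        }
      }
      x <- array(unlist(planes, use.names = FALSE),
                 c(dim(pr$m), sum(vapply(planes, function(q) dim(q)[3], numeric(1)))))
    }
    x
  })
  bind_batch(xs)
}

# ---- training loop ----------------------------------------------------

#' Train a generator variant with the masked adversarial + L1 objective
#'
#' Alternating discriminator/generator Adam updates with on-the-fly crops;
#' the total generator loss is `adversarial + lambda * L1` and both the L1
#' term and the discriminator's fake input use the mask-multiplied
#' generator output. Fully deterministic under `(seed, cfg, dataset)`.
#'
#' @param dataset A `usgan_dataset` (must provide `l` when training LSA2H).
#' @param variant Variant name (see [make_variant()]).
#' @param cfg A [train_config()].
#' @return A `usgan_gan` fit: generator, discriminator, history tibble
#'   (step, loss_d, loss_g_adv, loss_g_l1, val_l1), split indices, config.
#' @export
train_gan <- function(dataset, variant = "SA2H", cfg = train_config()) {
  rec1 <- dataset$records[[1]]
  img_h <- nrow(rec1$s)
  crop <- cfg$crop_size %||% min(dim(rec1$s))
  if (crop %% 2^cfg$n_down != 0)
    stopf("train_gan: crop size %d not divisible by 2^%d", crop, cfg$n_down)
  vs <- make_variant(variant, image_size = crop,
                     base_channels = cfg$base_channels, n_down = cfg$n_down)
  gcfg <- vs$cfg
  if ("l" %in% gcfg$inputs && is.null(rec1$l))
    stopf("train_gan: variant %s needs low-quality images; regenerate the dataset with lowquality = TRUE",
          variant)
  split <- split_dataset(dataset, cfg$train_frac, cfg$seed)
  preps <- lapply(dataset$records, prep_record, gcfg = gcfg)
  cond_ch <- input_channels(within_cfg_inputs(gcfg, cond_inputs(gcfg)))
  dcfg <- discriminator_config(1L + cond_ch, cfg$disc_base, cfg$disc_layers)

  withr::with_seed(cfg$seed, {
    gen <- build_generator(gcfg)
    disc <- build_discriminator(dcfg)
    adG <- adam_new(gen$params)
    adD <- adam_new(disc$params)
    hist <- vector("list", cfg$steps)
    val_l1 <- function() {
      tot <- 0
      for (i in split$val) {
        pr <- preps[[i]]
        x0 <- assemble_inputs(list(pr), gcfg)
        out <- generator_predict(gen, x0)
        tot <- tot + fidelity_loss(pr$y[, , 1], out[, , 1, 1], pr$m)
      }
      tot / max(1, length(split$val))
    }
    initial_val <- val_l1()
    vals <- tibble::tibble(step = 0L, val_l1 = initial_val)

    for (step in seq_len(cfg$steps)) {
      idx <- split$train[sample.int(length(split$train), cfg$batch_size,
                                    replace = TRUE)]
      ats <- lapply(idx, function(i) sample_crop(preps[[i]]$m, crop))
      batch <- lapply(seq_along(idx), function(k) {
        pr <- preps[[idx[k]]]
        list(x = crop_arr(pr$x, ats[[k]], crop),
             y = crop_arr(pr$y, ats[[k]], crop),
             m = crop_arr(pr$m, ats[[k]], crop))
      })
      x0 <- assemble_inputs(batch, gcfg)
      yb <- bind_batch(lapply(batch, `[[`, "y"))
      mb <- bind_batch(lapply(batch, function(b) array(b$m, c(dim(b$m), 1))))
      cond <- bind_batch(lapply(batch, function(b) {
        b$x   # deterministic planes only
      }))

      # --- generator update (discriminator frozen) ---
      tp <- new_tape()
      lg <- make_leaves(tp, gen$params)
      ld <- make_leaves(tp, disc$params)
      fake <- gen_forward(tp, lg, gcfg, x0)
      fakem <- ag_mul_const(tp, fake, mb)
      dstack <- ag_concat(tp, list(fakem, ag_leaf(tp, cond)))
      dlogit <- disc_forward(tp, ld, dcfg, dstack)
      adv <- if (cfg$non_saturating) ag_bce_mean(tp, dlogit, TRUE)
      else ag_scale(tp, ag_bce_mean(tp, dlogit, FALSE), -1)
      l1 <- ag_l1_const(tp, fakem, yb)
      lossG <- ag_axpby(tp, 1, adv, cfg$lambda_fidelity, l1)
      ag_backward(tp, lossG)
      upd <- adam_step(adG, gen$params, collect_grads(lg),
                       cfg$lr, cfg$beta1, cfg$beta2)
      adG <- upd$state; gen$params <- upd$params

      # --- discriminator update (fake detached) ---
      tp2 <- new_tape()
      ld2 <- make_leaves(tp2, disc$params)
      real_stack <- ag_leaf(tp2, abind_ch(yb * as_mask4(mb, yb), cond))
      fake_stack <- ag_leaf(tp2, abind_ch(fakem$val, cond))
      dr <- disc_forward(tp2, ld2, dcfg, real_stack)
      df <- disc_forward(tp2, ld2, dcfg, fake_stack)
      lossD <- ag_axpby(tp2, 0.5, ag_bce_mean(tp2, dr, TRUE),
                        0.5, ag_bce_mean(tp2, df, FALSE))
      ag_backward(tp2, lossD)
      updD <- adam_step(adD, disc$params, collect_grads(ld2),
                        cfg$lr, cfg$beta1, cfg$beta2)
      adD <- updD$state; disc$params <- updD$params

      hist[[step]] <- c(step = step, loss_d = lossD$val,
                        loss_g_adv = adv$val, loss_g_l1 = l1$val)
      if (step %% cfg$val_every == 0 || step == cfg$steps) {
        vals <- rbind(vals, tibble::tibble(step = step, val_l1 = val_l1()))
      }
    }
    history <- if (cfg$steps > 0)
      tibble::as_tibble(do.call(rbind, hist)) else
        tibble::tibble(step = integer(), loss_d = numeric(),
                       loss_g_adv = numeric(), loss_g_l1 = numeric())
    structure(list(generator = gen, discriminator = disc, variant = variant,
                   cfg = cfg, gcfg = gcfg, dcfg = dcfg,
                   history = history, validation = vals, split = split,
                   initial_val_l1 = initial_val),
              class = "usgan_gan")
  })
}

# concat along channel dim for plain (H,W,C,N) arrays
abind_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

as_mask4 <- function(mb, like) array(mb, dim(like))

ag_scale <- function(tape, x, a) {
  ag_node(tape, a * x$val, list(x), function(g) list(g * a))
}

#' @export
print.usgan_gan <- function(x, ...) {
  cat(sprintf("<usgan_gan> %s, %d steps, G %s / D %s params, final val L1 %.4f\n",
              x$variant, nrow(x$history),
              format(n_params(x$generator), big.mark = ","),
              format(n_params(x$discriminator), big.mark = ","),
              tail(x$validation$val_l1, 1)))
  invisible(x)
}

#' Generate B-mode predictions from a fitted generator
#'
#' @param object A `usgan_gan` fit.
#' @param dataset A `usgan_dataset` on the geometry the fit was trained on.
#' @param idx Record indices (default: the fit's validation split).
#' @param seed Seed for noise draws.
#' @param ... Unused.
#' @return List of 8-bit prediction matrices (masked).
#' @export
predict.usgan_gan <- function(object, dataset, idx = NULL, seed = 1, ...) {
  idx <- idx %||% object$split$val
  gcfg <- object$gcfg
  withr::with_seed(as.integer(seed), {
    lapply(idx, function(i) {
      pr <- prep_record(dataset$records[[i]], gcfg)
      x0 <- assemble_inputs(list(pr), gcfg)
      out <- generator_predict(object$generator, x0)[, , 1, 1]
      round(pmin(pmax((out + 1) * 127.5, 0), 255)) * dataset$records[[i]]$m
    })
  })
}
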
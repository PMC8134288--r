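# broom-style accessors for fitted objects and reports.

#' Tidy a fitted GAN: the per-step training history
#'
#' @param x A `usgan_gan`.
#' @param ... Unused.
#' @return Tibble with `step`, `loss_d`, `loss_g_adv`, `loss_g_l1`.
#' @export
tidy.usgan_gan <- function(x, ...) x$history

#' One-row summary of a fitted GAN
#'
#' @param x A `usgan_gan`.
#' @param ... Unused.
#' @return Tibble with variant, steps, parameter counts, final losses and
#'   initial/final held-out masked L1.
#' @export
glance.usgan_gan <- function(x, ...) {
  last <- if (nrow(x$history)) x$history[nrow(x$history), ] else
    tibble::tibble(loss_d = NA_real_, loss_g_adv = NA_real_,
                   loss_g_l1 = NA_real_)
  tibble::tibble(variant = x$variant, steps = nrow(x$history),
                 n_params_g = n_params(x$generator),
                 n_params_d = n_params(x$discriminator),
                 loss_d = last$loss_d, loss_g_adv = last$loss_g_adv,
                 loss_g_l1 = last$loss_g_l1,
                 val_l1_initial = x$initial_val_l1,
                 val_l1_final = tail(x$validation$val_l1, 1))
}

#' Tidy a metric report: the per-image metric table
#'
#' @param x A `usgan_report`.
#' @param ... Unused.
#' @export
tidy.usgan_report <- function(x, ...) x$per_image

#' One-row summary of a metric report
#'
#' @param x A `usgan_report`.
#' @param ... Unused.
#' @export
glance.usgan_report <- function(x, ...) {
  tibble::tibble(n_images = nrow(x$per_image),
                 psnr_mean = mean(x$per_image$psnr),
                 psnr_sd = sd(x$per_image$psnr),
                 mae_mean = mean(x$per_image$mae),
                 mae_sd = sd(x$per_image$mae),
                 pchi2_mean = mean(x$per_image$pchi2),
                 pchi2_sd = sd(x$per_image$pchi2),
                 fid = x$fid)
}

#' Tidy an ablation run: the variant metric table
#'
#' @param x A `usgan_ablation`.
#' @param ... Unused.
#' @export
tidy.usgan_ablation <- function(x, ...) x$table
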
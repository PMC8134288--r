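#' Train and evaluate a set of model variants under shared conditions
#'
#' Trains each variant with the same seed, data split and optimizer
#' settings, generates held-out predictions, and tabulates PSNR, masked
#' MAE, patch chi-squared (mean and sd over the held-out set), Frechet
#' feature distance, and trainable parameter counts — one row per variant.
#' Per-image values are kept so paired differences against the proposed
#' model can be inspected.
#'
#' @param dataset A `usgan_dataset`.
#' @param variants Character vector of variant names.
#' @param cfg A [train_config()] shared by all variants.
#' @param extractor Feature extractor for the set-level Frechet distance.
#' @param shadow_only Also compute patch chi-squared restricted to shadow
#'   patches (from each record's attenuation map).
#' @return A `usgan_ablation`: `table` (one row per variant), `per_image`,
#'   and the fitted models in `fits`.
#' @export
run_ablation <- function(dataset, variants, cfg = train_config(),
                         extractor = feature_extractor(),
                         shadow_only = FALSE) {
  fits <- list()
  rows <- list()
  per <- list()
  for (v in variants) {
    fit <- train_gan(dataset, v, cfg)
    fits[[v]] <- fit
    idx <- fit$split$val
    preds <- predict(fit, dataset, idx, seed = cfg$seed)
    targets <- lapply(idx, function(i) dataset$records[[i]]$y)
    mask <- dataset$records[[idx[1]]]$m
    rep <- metric_report(preds, targets, mask, extractor = extractor)
    pi <- rep$per_image
    pi$image <- idx[pi$image]
    pi <- tibble::add_column(pi, variant = v, .before = 1)
    if (shadow_only) {
      pi$pchi2_shadow <- vapply(seq_along(idx), function(k) {
        rec <- dataset$records[[idx[k]]]
        sm <- shadow_mask(rec$a, rec$m)
        if (sum(sm) == 0) return(NA_real_)
        pchi2(rec$y, preds[[k]], mask = sm)$value
      }, numeric(1))
    }
    per[[v]] <- pi
    rows[[v]] <- tibble::tibble(
      variant = v,
      n_params = n_params(fit$generator),
      psnr_mean = mean(rep$per_image$psnr), psnr_sd = sd(rep$per_image$psnr),
      mae_mean = mean(rep$per_image$mae), mae_sd = sd(rep$per_image$mae),
      pchi2_mean = mean(rep$per_image$pchi2), pchi2_sd = sd(rep$per_image$pchi2),
      fid = rep$fid)
  }
  structure(list(table = dplyr::bind_rows(rows),
                 per_image = dplyr::bind_rows(per),
                 fits = fits, cfg = cfg),
            class = "usgan_ablation")
}

#' @export
print.usgan_ablation <- function(x, ...) {
  cat("<usgan_ablation>\n")
  print(x$table)
  invisible(x)
}
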
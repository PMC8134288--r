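test_that("PSNR uses the linear peak, with the squared variant one flag away", {
  a <- matrix(100, 10, 10)
  expect_identical(psnr(a, a), Inf)
  b <- a + 16                       # MSE = 256
  expect_equal(psnr(a, b), 10 * log10(255 / 256), tolerance = 1e-12)
  expect_equal(psnr(a, b, peak = "squared"), 10 * log10(255^2 / 256),
               tolerance = 1e-12)
  # brute-force elementwise oracle on random pairs
  set.seed(1)
  for (r in 1:20) {
    y <- matrix(sample(0:255, 64, TRUE), 8, 8)
    z <- matrix(sample(0:255, 64, TRUE), 8, 8)
    mse <- 0
    for (k in seq_along(y)) mse <- mse + (y[k] - z[k])^2
    mse <- mse / length(y)
    expect_equal(psnr(y, z), 10 * log10(255 / mse), tolerance = 1e-12)
  }
  expect_error(psnr(a, matrix(0, 2, 2)), "shape")
})

test_that("PSNR is strictly decreasing in MSE and MAE satisfies metric axioms", {
  set.seed(2)
  y <- matrix(runif(100, 0, 255), 10, 10)
  offs <- c(1, 4, 9, 20)
  ps <- vapply(offs, function(o) psnr(y, y + o), numeric(1))
  expect_true(all(diff(ps) < 0))
  z <- matrix(runif(100, 0, 255), 10, 10)
  expect_equal(mae(y, y), 0)
  expect_equal(mae(y, y + 7), 7, tolerance = 1e-12)
  expect_gte(mae(y, z), 0)
  expect_equal(mae(y, z), mae(z, y))
  # masked + brute-force oracle
  m <- matrix(rbinom(100, 1, 0.6), 10, 10)
  expect_equal(mae(y, z, m), mean(abs(y - z)[m == 1]))
})

test_that("chi-squared histogram distance: identity, disjoint supports, symmetry, bound", {
  h <- intensity_hist(sample(0:255, 400, TRUE))
  expect_equal(chi2_hist(h, h), 0)
  # disjoint supports: each term contributes h^2/h = h, so the sum is
  # (sum hA + sum hB)/2 = 1 exactly for normalized histograms
  hA <- c(0.25, 0.75, 0, 0)
  hB <- c(0, 0, 0.5, 0.5)
  expect_identical(chi2_hist(hA, hB), 1)
  set.seed(3)
  for (r in 1:1000) {
    a <- stats::runif(50); a <- a / sum(a)
    b <- stats::runif(50); b <- b / sum(b)
    v <- chi2_hist(a, b)
    expect_identical(v, chi2_hist(b, a))
    expect_true(v >= 0 && v <= 1)
    # per-bin brute force on a subsample of iterations
    if (r %% 100 == 0) {
      acc <- 0
      for (l in 1:50) if (a[l] + b[l] > 0)
        acc <- acc + (a[l] - b[l])^2 / (a[l] + b[l])
      expect_equal(v, acc / 2, tolerance = 1e-12)
    }
  }
})

test_that("patch chi-squared: identity, disjoint constants, permutation invariance", {
  set.seed(4)
  y <- matrix(sample(0:255, 60 * 60, TRUE), 60, 60)
  pc <- pchi2(y, y)
  expect_equal(pc$value, 0)
  expect_true(all(pc$map == 0))
  # constants landing in different histogram bins: every patch distance 1
  pc1 <- pchi2(matrix(10, 40, 40), matrix(200, 40, 40))
  expect_equal(pc1$value, 1)
  expect_true(all(pc1$map == 1))
  # permutation within each 20x20 patch leaves histograms unchanged
  yp <- y
  for (i in 0:2) for (j in 0:2) {
    ri <- i * 20 + 1:20; ci <- j * 20 + 1:20
    yp[ri, ci] <- matrix(sample(y[ri, ci]), 20, 20)
  }
  expect_equal(pchi2(y, yp)$value, 0)
  expect_true(all(pchi2(y, matrix(sample(0:255, 3600, TRUE), 60, 60))$map >= 0))
  expect_true(all(pchi2(y, matrix(sample(0:255, 3600, TRUE), 60, 60))$map <= 1))
  expect_error(pchi2(matrix(0, 10, 10), matrix(0, 10, 10)), "smaller")
  # border tiles are dropped: 50x50 image has 2x2 complete patches
  expect_equal(dim(pchi2(matrix(0, 50, 50), matrix(0, 50, 50))$map), c(2L, 2L))
})

test_that("Frechet distance: identity, closed forms, permutation invariance", {
  set.seed(5)
  X <- matrix(rnorm(500 * 8), 500, 8)
  expect_lt(abs(fid(X, X)), 1e-6)
  # 1-D N(0,1) vs N(0,4): (sigma1 - sigma2)^2 = 1
  a <- matrix(rnorm(40000, 0, 1), ncol = 1)
  b <- matrix(rnorm(40000, 0, 2), ncol = 1)
  expect_lt(abs(fid(a, b) - 1), 0.1)
  # mean shift: |delta|^2
  d <- rep(0.5, 16)
  f1 <- matrix(rnorm(10000 * 16), 10000)
  f2 <- matrix(rnorm(10000 * 16), 10000) + rep(d, each = 10000)
  expect_lt(abs(fid(f1, f2) - sum(d^2)) / sum(d^2), 0.05)
  expect_gte(fid(f1, f2), 0)
  # joint permutation invariance
  p <- sample(10000)
  expect_equal(fid(f1[p, ], f2[p, ]), fid(f1, f2), tolerance = 1e-9)
  expect_error(fid(f1, f2[, 1:8]), "dimension")
})

test_that("the crop protocol produces the corner-anchored sub-crops", {
  img <- matrix(seq_len(512 * 512), 512, 512)
  cr <- fid_crops(img, factor = 1)
  expect_length(cr, 4)
  expect_true(all(vapply(cr, function(x) all(dim(x) == c(299, 299)), logical(1))))
  expect_equal(attr(cr, "offsets"),
               rbind(c(0, 0), c(0, 213), c(213, 0), c(213, 213)))
  expect_identical(cr[[1]], img[1:299, 1:299])
  expect_identical(cr[[4]], img[214:512, 214:512])
  # 1024: center crop spans rows/cols 257..768 (1-based)
  big <- matrix(0, 1024, 1024)
  big[257:768, 257:768] <- 1
  crb <- fid_crops(big, factor = 1)
  expect_true(all(vapply(crb, function(x) all(x == 1), logical(1))))
  # desk-scale common factor
  crd <- fid_crops(matrix(0, 128, 128))
  expect_equal(dim(crd[[1]]), c(75L, 75L))
  expect_error(fid_crops(matrix(0, 16, 16), factor = 1), "too small")
})

test_that("feature extractors are deterministic and typed", {
  set.seed(7)
  img <- matrix(runif(64 * 64, 0, 255), 64, 64)
  fx <- feature_extractor("random-projection", dim = 32, seed = 4)
  expect_identical(fx(img), fx(img))
  f <- fx(replicate(3, img, simplify = FALSE))
  expect_equal(dim(f), c(3L, 32L))
  hm <- feature_extractor("histogram-moments")
  fc <- hm(matrix(120, 16, 16))
  expect_equal(unname(fc[1, 1]), 120)
  expect_equal(unname(fc[1, 2]), 0)
  expect_error(feature_extractor("inception-v3"), "pretrained weights")
})

test_that("paired differences: mean of differences equals difference of means", {
  set.seed(8)
  per <- rbind(
    tibble::tibble(variant = "SA2H", image = 1:10, psnr = rnorm(10, 28),
                   mae = rnorm(10, 6), pchi2 = runif(10)),
    tibble::tibble(variant = "SA2H-att", image = 1:10, psnr = rnorm(10, 25),
                   mae = rnorm(10, 9), pchi2 = runif(10, 0.2)))
  pd <- paired_differences(per, "SA2H")
  expect_equal(mean(pd$d_psnr),
               mean(per$psnr[per$variant == "SA2H-att"]) -
                 mean(per$psnr[per$variant == "SA2H"]),
               tolerance = 1e-12)
  expect_equal(nrow(pd), 10)
})

test_that("metric_report aggregates are recomputable from per-image entries", {
  set.seed(9)
  imgs <- replicate(4, matrix(sample(0:255, 40 * 40, TRUE), 40, 40),
                    simplify = FALSE)
  preds <- lapply(imgs, function(m) pmin(pmax(m + sample(-20:20, 1600, TRUE), 0), 255))
  rp <- metric_report(preds, imgs)
  expect_s3_class(tidy(rp), "tbl_df")
  g <- glance(rp)
  expect_equal(g$psnr_mean, mean(rp$per_image$psnr))
  expect_equal(g$pchi2_sd, sd(rp$per_image$pchi2))
  expect_true(is.finite(g$fid))
})
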
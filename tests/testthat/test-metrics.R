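test_that("entropy attains its analytic bounds and hand values", {
  expect_identical(img_entropy(slice_image(matrix(7, 16, 16))), 0)
  uniform <- slice_image(matrix(rep(0:255, each = 256), 256))
  expect_equal(img_entropy(uniform), 8)
  two_level <- slice_image(matrix(c(0, 255), 16, 16))
  expect_equal(img_entropy(two_level), 1)   # 50/50 split of two levels
})

test_that("entropy is bounded by log2(occupied bins), equality iff equiprobable", {
  ## exhaustive check on 4-level toy images of 4 pixels
  lv <- expand.grid(a = 0:3, b = 0:3, c = 0:3, d = 0:3)
  for (i in seq_len(nrow(lv))) {
    v <- as.numeric(lv[i, ])
    e <- img_entropy(slice_image(matrix(v, 2, 2), bit_depth = 4))
    k <- length(unique(v))
    expect_lte(e, log2(k) + 1e-12)
    counts <- table(v)
    if (length(unique(counts)) == 1L) expect_equal(e, log2(k))
  }
})

test_that("population STD matches closed forms and ignores pixel order", {
  expect_identical(img_std(slice_image(matrix(42, 8, 8))), 0)
  half <- slice_image(matrix(c(rep(0, 32), rep(255, 32)), 8, 8))
  expect_equal(img_std(half), 127.5)
  set.seed(10)
  X <- matrix(runif(64, 0, 255), 8)
  Xp <- matrix(sample(X), 8)
  expect_equal(img_std(slice_image(X)), img_std(slice_image(Xp)))
})

test_that("PSNR follows its defining algebra", {
  s0 <- slice_image(matrix(0, 16, 16)); f255 <- slice_image(matrix(255, 16, 16))
  expect_equal(img_psnr(s0, f255), 0)                 # RMSE = 255 on 8-bit
  expect_identical(img_psnr(f255, f255), Inf)         # identical-image sentinel
  ## doubling the RMSE lowers PSNR by exactly 20 log10(2)
  base <- matrix(100, 16, 16)
  p1 <- img_psnr(slice_image(base), slice_image(base + 5))
  p2 <- img_psnr(slice_image(base), slice_image(base + 10))
  expect_equal(p1 - p2, 20 * log10(2), tolerance = 1e-12)
  expect_error(img_psnr(s0, slice_image(matrix(0, 8, 8))), "dimensions")
  ## per-image-max peak option
  f <- slice_image(matrix(c(rep(100, 128), rep(200, 128)), 16))
  expect_lt(img_psnr(s0, f, peak = "image_max"), img_psnr(s0, f))
})

test_that("SSIM attains 1 on identical images and ~0 on independent fields", {
  img <- quantize_slice(slice_image(matrix(runif(64 * 64, 0, 255), 64)))
  expect_identical(ssim_pair(img, img, img), 1)
  expect_equal(ssim_pair(img, img, img, window_radius = 5), 1)
  ## Monte-Carlo oracle: independent large random fields decorrelate
  set.seed(11)
  a <- slice_image(matrix(runif(256 * 256, 0, 255), 256))
  b <- slice_image(matrix(runif(256 * 256, 0, 255), 256))
  f <- slice_image(matrix(runif(256 * 256, 0, 255), 256))
  ## centre the fields so the luminance term does not dominate
  am <- slice_image(pxm(a) - mean(pxm(a)) + 1)
  fm <- slice_image(pxm(f) - mean(pxm(f)) + 1)
  s_af <- gliofuse:::ssim_global(pxm(am), pxm(fm), (0.01 * 255)^2, (0.03 * 255)^2)
  expect_lt(abs(s_af), 0.05)
  ## symmetry of the per-pair term
  expect_equal(gliofuse:::ssim_global(pxm(a), pxm(f), 6.5025, 58.5225),
               gliofuse:::ssim_global(pxm(f), pxm(a), 6.5025, 58.5225))
})

test_that("windowed SSIM with a full-image window equals the global value", {
  set.seed(12)
  a <- quantize_slice(slice_image(matrix(runif(32 * 32, 0, 255), 32)))
  f <- quantize_slice(slice_image(matrix(runif(32 * 32, 0, 255), 32)))
  g <- ssim_pair(a, a, f)
  w <- ssim_pair(a, a, f, window_radius = 64)   # window covers the image
  expect_equal(w, g, tolerance = 1e-12)
})

test_that("PSNR and SSIM degrade monotonically with perturbation size", {
  set.seed(13)
  src <- quantize_slice(slice_image(matrix(runif(64 * 64, 30, 220), 64)))
  noise <- matrix(rnorm(64 * 64), 64)
  mags <- c(0, 2, 5, 10, 20, 40)
  psnrs <- ssims <- numeric(length(mags))
  for (i in seq_along(mags)) {
    f <- slice_image(pmin(pmax(pxm(src) + mags[i] * noise, 0), 255))
    psnrs[i] <- img_psnr(src, f)
    ssims[i] <- ssim_pair(src, src, f)
  }
  expect_identical(psnrs[1], Inf)
  expect_equal(ssims[1], 1)
  expect_true(all(diff(psnrs) < 0))
  expect_true(all(diff(ssims) < 0))
})

test_that("quality_table averages per method and flags the column maxima", {
  d <- data.frame(subject_id = rep(c("s1", "s2"), each = 2),
                  method = rep(c("PCA", "LRD"), 2),
                  entropy = c(5, 6, 5.5, 6.5), std = c(40, 60, 42, 58),
                  psnr = c(30, Inf, 32, 20), ssim = c(0.9, 0.8, 0.88, 0.82))
  q <- quality_table(d)
  expect_equal(q$summary$entropy[q$summary$method == "LRD"], 6.25)
  ## infinite PSNR excluded from the mean, counted
  lrd_row <- q$summary[q$summary$method == "LRD", ]
  expect_equal(lrd_row$psnr, 20)
  expect_equal(lrd_row$psnr_inf_n, 1L)
  ## brute-force argmax flags
  for (col in c("entropy", "std", "psnr", "ssim"))
    expect_equal(unname(q$best[col]),
                 q$summary$method[which.max(q$summary[[col]])])
  ## single subject: averages equal the single values
  one <- d[d$subject_id == "s1", ]
  q1 <- quality_table(one)
  expect_equal(q1$summary$ssim, one$ssim)
})
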
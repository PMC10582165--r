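test_that("control-region normalization solves the two linear constraints", {
  set.seed(1)
  X <- matrix(runif(64 * 64, 0, 255), 64)
  mask <- matrix(FALSE, 64, 64); mask[20:40, 20:40] <- TRUE
  ## already at target -> identity
  v <- X[mask]
  X1 <- (X - mean(v)) / sqrt(mean((v - mean(v))^2)) * 10 + 100
  img1 <- slice_image(pmax(X1, 0))
  out1 <- normalize_control_region(img1, mask)
  expect_equal(pxm(out1), pxm(img1), tolerance = 1e-12)
  ## control mean 200, STD 20 -> a = 0.5, b = 0 (hand solution)
  Y <- X1 * 2
  out2 <- normalize_control_region(slice_image(Y), mask)
  expect_equal(pxm(out2), 0.5 * Y, tolerance = 1e-12)
  ## order preservation
  img <- slice_image(X)
  outp <- pxm(normalize_control_region(img, mask))
  i <- sample(length(X), 500); j <- sample(length(X), 500)
  expect_true(all(sign(outp[i] - outp[j]) == sign(X[i] - X[j])))
  ## zero-variance control region: mean-only shift with warning
  Z <- X; Z[mask] <- 50
  expect_warning(outz <- normalize_control_region(slice_image(Z), mask),
                 "zero-variance")
  expect_equal(mean(pxm(outz)[mask]), 100)
})

test_that("RSC is invariant to global affine intensity changes after normalization", {
  s <- generate_subject(phantom_config(image_size = 64, noise_sigma = 5), "LGG", 7)
  r1 <- rsc(normalize_control_region(s$adc, s$wm_mask), s$rois)
  aff <- slice_image(3.7 * pxm(s$adc) + 42)
  r2 <- rsc(normalize_control_region(aff, s$wm_mask), s$rois)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("landmark fitting recovers identity, translation, and smooth warps", {
  set.seed(2)
  fx <- cbind(runif(20, 8, 55), runif(20, 8, 55))
  ## identity
  tr0 <- fit_landmark_bspline(landmark_set(fx, fx), c(64, 64), 16)
  expect_lt(tr0$residual_rms, 1e-8)
  expect_lt(max(abs(displacement_at(tr0, fx))), 1e-8)
  ## uniform translation: displacement ~ (+5, -3) everywhere inside the hull
  tr1 <- fit_landmark_bspline(landmark_set(fx, sweep(fx, 2, c(5, -3), `+`)),
                              c(64, 64), 16)
  expect_lt(tr1$residual_rms, 0.1)
  d <- displacement_at(tr1, cbind(c(15, 30, 45), c(15, 30, 45)))
  expect_equal(d[, 1], rep(5, 3), tolerance = 1e-6)
  expect_equal(d[, 2], rep(-3, 3), tolerance = 1e-6)
  ## known quadratic warp, dense landmark grid: residual below half a pixel
  fx2 <- as.matrix(expand.grid(seq(5, 60, 5), seq(5, 60, 5)))
  warp <- function(p) cbind(p[, 1] + 0.001 * (p[, 1] - 32)^2,
                            p[, 2] - 0.0008 * (p[, 2] - 32)^2 +
                              0.002 * (p[, 1] - 32))
  tr2 <- fit_landmark_bspline(landmark_set(fx2, warp(fx2)), c(64, 64), 8)
  expect_lt(tr2$residual_rms, 0.5)
  ## brute-force check of the fitted warp at the landmark sites
  phi <- fx2 + displacement_at(tr2, fx2)
  expect_lt(sqrt(mean(rowSums((phi - warp(fx2))^2))), 0.5)
})

test_that("degenerate landmark configurations are rejected with a diagnostic", {
  expect_error(fit_landmark_bspline(
    landmark_set(cbind(1:3, 1:3), cbind(1:3, 1:3)), c(64, 64)), "at least 4")
  coll <- cbind(1:6, 2 * (1:6))
  expect_error(fit_landmark_bspline(landmark_set(coll, coll), c(64, 64)),
               "collinear")
  expect_error(landmark_set(rbind(c(1, 1), c(1, 1), c(2, 2), c(3, 4)),
                            cbind(1:4, 1:4)), "duplicate")
})

test_that("resampling is exact for identity and integer shifts, accurate in round trips", {
  set.seed(3)
  img <- slice_image(matrix(runif(64 * 64, 0, 255), 64))
  tr <- bspline_transform(16, c(64, 64))
  expect_lt(max(abs(pxm(resample_slice(img, tr)) - pxm(img))), 1e-6)
  ## constructed integer translation: interior equals the shifted original
  trs <- bspline_transform(16, c(64, 64))
  trs$disp_r[] <- 5; trs$disp_c[] <- -3
  B <- pxm(resample_slice(img, trs)); A <- pxm(img)
  expect_lt(max(abs(B[1:59, 4:64] - A[6:64, 1:61])), 1e-9)
  ## fractional-shift round trip on a band-limited image: < 1e-3 of range
  sm <- smooth_image(64)
  t1 <- bspline_transform(16, c(64, 64)); t1$disp_r[] <- 2.5; t1$disp_c[] <- -1.25
  t2 <- bspline_transform(16, c(64, 64)); t2$disp_r[] <- -2.5; t2$disp_c[] <- 1.25
  rt <- pxm(resample_slice(resample_slice(sm, t1), t2))
  int <- 10:55
  rng <- diff(range(pxm(sm)))
  expect_lt(max(abs(rt[int, int] - pxm(sm)[int, int])), 1e-3 * rng)
})

test_that("registering a jittered SWI back onto the ADC frame corrects the tumour position", {
  cfg_j <- phantom_config(image_size = 128, noise_sigma = 0, contrast_sd = 0,
                          misalignment_max = 5)
  cfg_0 <- phantom_config(image_size = 128, noise_sigma = 0, contrast_sd = 0)
  for (seed in c(11, 23, 37)) {
    sj <- generate_subject(cfg_j, "HGG", seed)
    s0 <- generate_subject(cfg_0, "HGG", seed)   # same geometry, no jitter
    reg <- register_landmarks(sj$swi, sj$landmarks, grid_spacing = 32)
    centroid <- function(X) {
      w <- which(abs(X - 60) < 20, arr.ind = TRUE)  # HGG SWI tumour level
      colMeans(w) - 1
    }
    before <- sqrt(sum((centroid(pxm(sj$swi)) - sj$tumor_center)^2))
    after <- sqrt(sum((centroid(pxm(reg$image)) - sj$tumor_center)^2))
    expect_gt(before, after)
    expect_lt(after, 1)
    ## registered slice matches the unjittered ground truth in the interior
    int <- 20:108
    expect_lt(mean(abs(pxm(reg$image)[int, int] - pxm(s0$swi)[int, int])), 1.5)
  }
})

test_that("landmark JSON round-trips", {
  lm <- landmark_set(cbind(c(1.5, 10, 20, 30), c(2, 12, 22, 30)),
                     cbind(c(2.5, 11, 21, 31), c(1, 11, 21, 29)),
                     label = c("ac", "pc", "cc", "vent"))
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks_json(lm, path)
  lm2 <- read_landmarks_json(path)
  expect_equal(lm2$fixed, lm$fixed, ignore_attr = TRUE)
  expect_equal(lm2$moving, lm$moving, ignore_attr = TRUE)
  expect_equal(lm2$label, lm$label)
})
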
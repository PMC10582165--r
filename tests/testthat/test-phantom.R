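test_that("noise-free subjects reproduce the configured tissue means exactly", {
  cfg <- cfg_noise_free()
  s <- generate_subject(cfg, "LGG", 123)
  expect_equal(mean_roi_intensity(s$adc, s$rois$tumor), 140)
  expect_equal(mean_roi_intensity(s$adc, s$rois$wm), 100)
  expect_equal(mean_roi_intensity(s$swi, s$rois$tumor), 105)
  h <- generate_subject(cfg, "HGG", 321)
  expect_equal(mean_roi_intensity(h$adc, h$rois$tumor), 80)

  ## hand evaluation of the contrast ratio on configured constants
  cm <- list(ADC = c(brain = 115, wm = 100, tumor_lgg = 150, tumor_hgg = 80),
             SWI = c(brain = 110, wm = 120, tumor_lgg = 105, tumor_hgg = 60))
  s2 <- generate_subject(cfg_noise_free(contrast_means = cm), "LGG", 5)
  expect_equal(rsc(s2$adc, s2$rois), 0.5)
})

test_that("subject generation is deterministic given (config, grade, seed)", {
  cfg <- phantom_config(image_size = 64, noise_sigma = 8, seed = 2)
  a <- generate_subject(cfg, "HGG", 99)
  b <- generate_subject(cfg, "HGG", 99)
  expect_identical(pxm(a$adc), pxm(b$adc))
  expect_identical(pxm(a$swi), pxm(b$swi))
  expect_identical(a$rois, b$rois)
  expect_identical(a$age, b$age)
})

test_that("invalid grades and oversized tumours are rejected", {
  cfg <- cfg_noise_free()
  expect_error(generate_subject(cfg, "GBM", 1), "grade")
  big <- cfg_noise_free()
  big$tumor_radius_range <- c(30, 40)   # inner region of a 64-px slice is ~16.6
  expect_error(generate_subject(big, "LGG", 1), "exceeds")
})

test_that("cohort HGG counts equal round(n * fraction) for all n up to 200", {
  ## exhaustive count check without generating images
  for (n in c(1:20, 50, 96, 137, 200)) {
    for (f in c(0, 0.25, 0.5, 0.593, 0.8, 1)) {
      cfg <- phantom_config(image_size = 64, n_subjects = n, hgg_fraction = f,
                            noise_sigma = 0, contrast_sd = 0, seed = 3)
      n_hgg <- round(n * f)
      grades <- c(rep("HGG", n_hgg), rep("LGG", n - n_hgg))
      expect_length(grades, n)
      expect_equal(sum(grades == "HGG"), round(n * f))
    }
  }
  ## and on actually generated cohorts at the study's size
  co <- generate_cohort(phantom_config(image_size = 64, n_subjects = 96))
  g <- vapply(co, `[[`, "", "grade")
  expect_equal(sum(g == "HGG"), 57)
  expect_equal(sum(g == "LGG"), 39)
  co0 <- generate_cohort(phantom_config(image_size = 64, n_subjects = 10,
                                        hgg_fraction = 0))
  expect_true(all(vapply(co0, `[[`, "", "grade") == "LGG"))
  co5 <- generate_cohort(phantom_config(image_size = 64, n_subjects = 10,
                                        hgg_fraction = 0.5))
  expect_equal(sum(vapply(co5, `[[`, "", "grade") == "HGG"), 5)
})

test_that("noise-free RSC difference between grades matches the design exactly", {
  cfg <- cfg_noise_free()
  sl <- generate_subject(cfg, "LGG", 11)
  sh <- generate_subject(cfg, "HGG", 12)
  ## (140-100)/100 - (80-100)/100 = 0.6 by the default contrast means
  expect_equal(rsc(sl$adc, sl$rois) - rsc(sh$adc, sh$rois), 0.6)
})

test_that("Rician noise is positively biased, seeded, and an identity at sigma 0", {
  img <- slice_image(matrix(100, 320, 320))   # ~1e5 pixels at SNR 10
  expect_identical(add_rician_noise(img, 0, seed = 1), img)
  n1 <- add_rician_noise(img, 10, seed = 7)
  n2 <- add_rician_noise(img, 10, seed = 7)
  expect_identical(pxm(n1), pxm(n2))
  ## Monte-Carlo oracle: the Rician mean at SNR 10 exceeds the true signal
  expect_gt(mean(pxm(n1)), 100)
  expect_error(add_rician_noise(img, -1), "sigma")
})

test_that("noise fields of the two modalities are uncorrelated", {
  cfg_n <- phantom_config(image_size = 256, noise_sigma = 10, seed = 5)
  cfg_0 <- phantom_config(image_size = 256, noise_sigma = 0, seed = 5)
  sn <- generate_subject(cfg_n, "LGG", 42)
  s0 <- generate_subject(cfg_0, "LGG", 42)
  ## correlate inside the constant-intensity white-matter annulus, where the
  ## Rician bias is flat -- elsewhere the shared tissue layout makes the
  ## (deterministic) bias fields of the two modalities co-vary
  wm <- s0$wm_mask
  ra <- (pxm(sn$adc) - pxm(s0$adc))[wm]
  rb <- (pxm(sn$swi) - pxm(s0$swi))[wm]
  expect_gt(length(ra), 10000)
  expect_lt(abs(stats::cor(ra, rb)), 0.02)
})

test_that("config invariants are enforced", {
  expect_error(phantom_config(image_size = 32), "image_size")
  expect_error(phantom_config(hgg_fraction = 1.2), "hgg_fraction")
  expect_error(phantom_config(noise_sigma = -1), "noise_sigma")
  ## contrast directions: LGG below HGG is rejected on either modality
  cm <- list(ADC = c(brain = 115, wm = 100, tumor_lgg = 70, tumor_hgg = 80),
             SWI = c(brain = 110, wm = 120, tumor_lgg = 105, tumor_hgg = 60))
  expect_error(phantom_config(contrast_means = cm), "LGG")
  cm2 <- list(ADC = c(brain = 115, wm = 100, tumor_lgg = 140, tumor_hgg = 110),
              SWI = c(brain = 110, wm = 120, tumor_lgg = 105, tumor_hgg = 60))
  expect_error(phantom_config(contrast_means = cm2), "white matter")
})

test_that("tumour and white-matter ROIs are disjoint and written/read as JSON", {
  s <- generate_subject(cfg_noise_free(), "LGG", 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_rois_json(s$rois, path)
  r2 <- read_rois_json(path)
  expect_equal(r2$tumor, s$rois$tumor, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(r2$wm, s$rois$wm, tolerance = 1e-12, ignore_attr = TRUE)
})
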
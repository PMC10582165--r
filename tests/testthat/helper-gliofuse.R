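## shared test helpers; fixtures are generated in code, never stored

pxm <- function(image) {
  m <- as.matrix(image)
  attributes(m) <- list(dim = dim(m))
  m
}

## small noise-free phantom config (deterministic tumours)
cfg_noise_free <- function(size = 64, ...) {
  phantom_config(image_size = size, noise_sigma = 0, contrast_sd = 0, ...)
}

## a smooth band-limited test image (safe for interpolation accuracy checks)
smooth_image <- function(n = 64) {
  r <- matrix(0:(n - 1), n, n); c <- t(r)
  slice_image(100 + 60 * sin(2 * pi * r / 24) * cos(2 * pi * c / 20))
}

## matched clean/noisy patch sets cut from phantom ADC slices
make_patch_pairs <- function(n, sigma, seed0, side = 16, size = 64) {
  cfg <- cfg_noise_free(size)
  clean <- vector("list", n); noisy <- vector("list", n)
  set.seed(seed0)
  offs <- cbind(sample(seq_len(size - side), n, replace = TRUE),
                sample(seq_len(size - side), n, replace = TRUE))
  for (i in seq_len(n)) {
    s <- generate_subject(cfg, if (i %% 2) "LGG" else "HGG", seed0 + i)
    p <- pxm(s$adc)[offs[i, 1]:(offs[i, 1] + side - 1),
                    offs[i, 2]:(offs[i, 2] + side - 1)]
    clean[[i]] <- p
    noisy[[i]] <- pxm(add_rician_noise(slice_image(p), sigma,
                                       seed = seed0 + 70000 + i))
  }
  list(clean = clean, noisy = noisy)
}

## binormal RSC records with a designed population AUC
binormal_records <- function(auc, n_per_group, sd = 0.2, seed = 1) {
  delta <- stats::qnorm(auc) * sqrt(2) * sd
  set.seed(seed)
  data.frame(rsc = c(stats::rnorm(n_per_group, delta, sd),
                     stats::rnorm(n_per_group, 0, sd)),
             grade = rep(c("LGG", "HGG"), each = n_per_group))
}

## the null phantom: identical tumour contrast for both grades
cfg_null <- function(size = 64, noise_sigma = 10, seed = 1) {
  phantom_config(image_size = size, noise_sigma = noise_sigma, seed = seed,
                 contrast_means = list(
                   ADC = c(brain = 115, wm = 100, tumor_lgg = 80, tumor_hgg = 80),
                   SWI = c(brain = 110, wm = 120, tumor_lgg = 60, tumor_hgg = 60)))
}
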
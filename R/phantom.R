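#' Configuration of the synthetic glioma cohort generator
#'
#' The generator emulates the study design the pipeline was built for: paired
#' co-registered ADC-map / SWI slices per subject, one tumour whose mean
#' intensity relative to white matter depends on grade, Rician magnitude
#' noise, and (optionally) a small spatial misalignment of the SWI slice.
#' Contrast directions are fixed by the clinical literature: low-grade
#' gliomas (LGG) are brighter than high-grade (HGG) on both modalities, LGG
#' tumours are brighter than white matter on ADC maps, and HGG tumours are
#' darker than white matter on both.
#'
#' @param image_size Pixels per side (square slice), >= 64. Default 256.
#' @param n_subjects Cohort size. Default 96.
#' @param hgg_fraction Proportion of high-grade subjects in `[0, 1]`.
#'   Default 0.593.
#' @param tumor_radius_range Tumour disk radius range in pixels; default
#'   6 %--10 % of `image_size`.
#' @param contrast_means Named list with elements `ADC` and `SWI`, each a
#'   named vector `c(brain, wm, tumor_lgg, tumor_hgg)` of mean intensities on
#'   the 8-bit scale. Defaults place the grades about 0.6 RSC units apart on
#'   the ADC map. Setting the two grade means equal (below the white-matter
#'   mean) defines the null design -- a cohort with no grade effect -- used
#'   for statistical calibration.
#' @param contrast_sd Between-subject standard deviation of the tumour mean
#'   intensity (one severity draw per subject, shared across modalities).
#'   The default 26 puts the designed noise-free ADC-RSC separation at a
#'   population AUC of about 0.95. Set 0 for fully deterministic tumours.
#' @param noise_sigma Rician noise scale in intensity units (>= 0).
#'   Default 8.
#' @param misalignment_max Maximum pixel displacement of the random rigid
#'   jitter applied to the SWI slice; 0 (default) disables it.
#' @param seed Integer master seed; per-subject seeds are derived from it.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L,
                           n_subjects = 96L,
                           hgg_fraction = 0.593,
                           tumor_radius_range = NULL,
                           contrast_means = NULL,
                           contrast_sd = 26,
                           noise_sigma = 8,
                           misalignment_max = 0,
                           seed = 1L) {
  if (image_size < 64L) stop("phantom_config: image_size must be >= 64")
  if (hgg_fraction < 0 || hgg_fraction > 1)
    stop("phantom_config: hgg_fraction must lie in [0, 1]")
  if (noise_sigma < 0) stop("phantom_config: noise_sigma must be >= 0")
  if (contrast_sd < 0) stop("phantom_config: contrast_sd must be >= 0")
  if (misalignment_max < 0) stop("phantom_config: misalignment_max >= 0")
  if (is.null(tumor_radius_range))
    tumor_radius_range <- round(c(0.06, 0.10) * image_size)
  if (length(tumor_radius_range) != 2L || diff(tumor_radius_range) < 0 ||
      tumor_radius_range[1] < 2)
    stop("phantom_config: tumor_radius_range must be increasing and >= 2 px")
  if (is.null(contrast_means))
    contrast_means <- list(
      ADC = c(brain = 115, wm = 100, tumor_lgg = 140, tumor_hgg = 80),
      SWI = c(brain = 110, wm = 120, tumor_lgg = 105, tumor_hgg = 60))
  ## clinical contrast directions; equality of the two grade means is the
  ## explicit null design (no grade effect), used for calibration studies
  for (mod in c("ADC", "SWI")) {
    cm <- contrast_means[[mod]]
    if (is.null(cm) || !all(c("brain", "wm", "tumor_lgg", "tumor_hgg") %in% names(cm)))
      stop("phantom_config: contrast_means$", mod,
           " needs brain, wm, tumor_lgg, tumor_hgg")
    if (cm[["tumor_lgg"]] < cm[["tumor_hgg"]])
      stop("phantom_config: LGG tumour mean must not be below the HGG mean (", mod, ")")
    if (cm[["tumor_hgg"]] >= cm[["wm"]])
      stop("phantom_config: HGG tumour must be darker than white matter (", mod, ")")
  }
  null_design <- contrast_means$ADC[["tumor_lgg"]] == contrast_means$ADC[["tumor_hgg"]]
  if (!null_design && contrast_means$ADC[["tumor_lgg"]] <= contrast_means$ADC[["wm"]])
    stop("phantom_config: LGG tumour must be brighter than white matter on ADC")
  structure(list(image_size = as.integer(image_size),
                 n_subjects = as.integer(n_subjects),
                 hgg_fraction = hgg_fraction,
                 tumor_radius_range = as.numeric(tumor_radius_range),
                 contrast_means = contrast_means,
                 contrast_sd = contrast_sd,
                 noise_sigma = noise_sigma,
                 misalignment_max = misalignment_max,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf(paste0("<phantom_config> %d subjects (%.1f%% HGG), %dx%d px, ",
                     "noise sigma %.3g, tumour SD %.3g, misalignment <= %.3g px\n"),
              x$n_subjects, 100 * x$hgg_fraction, x$image_size, x$image_size,
              x$noise_sigma, x$contrast_sd, x$misalignment_max))
  invisible(x)
}

## fixed slice geometry for a given image size (memoized: identical for
## every subject of a cohort)
.geometry_cache <- new.env(parent = emptyenv())

phantom_geometry <- function(s) {
  key <- as.character(s)
  g <- .geometry_cache[[key]]
  if (!is.null(g)) return(g)
  g <- phantom_geometry_build(s)
  .geometry_cache[[key]] <- g
  g
}

phantom_geometry_build <- function(s) {
  ctr <- (s - 1) / 2
  r <- (seq_len(s) - 1) - ctr
  d2 <- outer(r^2, r^2, `+`)
  brain <- outer(r^2 / (0.45 * s)^2, r^2 / (0.40 * s)^2, `+`) <= 1
  wm <- d2 >= (0.26 * s)^2 & d2 <= (0.36 * s)^2 & brain
  list(size = s, center = ctr, brain = brain, wm = wm,
       inner_radius = 0.26 * s, wm_mid = 0.31 * s,
       wm_roi_radius = max(2, round(0.03 * s)))
}

## Rician magnitude noise around the current RNG state (no reseeding)
rician <- function(X, sigma) {
  if (sigma <= 0) return(X)
  n <- length(X)
  sqrt((X + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
}

#' Add Rician noise to a slice
#'
#' Magnitude-MRI noise model: each pixel is replaced by the magnitude of a
#' complex Gaussian perturbation of the true signal,
#' `sqrt((x + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma)`. The output is
#' re-quantized onto the slice's gray-level grid. Positively biased at low
#' signal-to-noise ratio.
#'
#' @param image A [slice_image()].
#' @param sigma Noise scale in intensity units (>= 0). `sigma = 0` returns
#'   the input unchanged.
#' @param seed Integer seed making the noise field reproducible.
#' @return A noisy `slice_image`.
#' @export
add_rician_noise <- function(image, sigma, seed = 1L) {
  if (sigma < 0) stop("add_rician_noise: sigma must be >= 0")
  if (sigma == 0) return(image)
  X <- px(image)
  noisy <- with_seed(seed, rician(X, sigma))
  quantize_slice(reslice(image, matrix(noisy, nrow(X), ncol(X))))
}

#' Generate one synthetic subject
#'
#' Builds a brain-ellipse background with a white-matter annulus and a single
#' disk tumour whose mean intensity is drawn from the configured
#' per-(modality, grade) contrast plus a subject-level severity deviation,
#' applies Rician noise independently per modality, and attaches three tumour
#' and three white-matter circular ROIs. Deterministic given
#' `(config, grade, subject_seed)`.
#'
#' @param config A [phantom_config()].
#' @param grade `"LGG"` or `"HGG"`.
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Optional identifier string.
#' @return An object of class `subject_record` with elements `adc`, `swi`,
#'   `rois`, `grade`, `sex`, `age`, tissue masks, and (when misalignment is
#'   enabled) the landmark pairs relating the jittered SWI to the ADC frame.
#' @export
generate_subject <- function(config, grade, subject_seed,
                             subject_id = sprintf("S%05d", subject_seed %% 100000L)) {
  if (!grade %in% c("LGG", "HGG")) stop("generate_subject: grade must be LGG or HGG")
  s <- config$image_size
  geo <- phantom_geometry(s)
  if (max(config$tumor_radius_range) >= geo$inner_radius)
    stop("generate_subject: tumor radius range exceeds the brain mask interior")

  with_seed(subject_seed, {
    r_t <- stats::runif(1, config$tumor_radius_range[1], config$tumor_radius_range[2])
    ang <- stats::runif(1, 0, 2 * pi)
    dmax <- max(0, geo$inner_radius - r_t - 2)
    dist <- stats::runif(1, 0, dmax)
    tc <- geo$center + dist * c(cos(ang), sin(ang))   # (row, col), 0-based
    zsub <- if (config$contrast_sd > 0) stats::rnorm(1) else 0
    sex <- sample(c("M", "F"), 1)
    age <- sample(36:84, 1)

    tumor <- circle_mask(s, s, tc[1], tc[2], r_t)
    paint <- function(cm) {
      tv <- cm[[if (grade == "LGG") "tumor_lgg" else "tumor_hgg"]] +
        zsub * config$contrast_sd
      X <- matrix(0, s, s)
      X[geo$brain] <- cm[["brain"]]
      X[geo$wm] <- cm[["wm"]]
      X[tumor] <- tv
      pmin(pmax(X, 0), 255)
    }
    adc_px <- rician(paint(config$contrast_means$ADC), config$noise_sigma)
    swi_px <- rician(paint(config$contrast_means$SWI), config$noise_sigma)

    adc <- quantize_slice(slice_image(adc_px, modality = "ADC"))
    swi <- quantize_slice(slice_image(swi_px, modality = "SWI"))

    landmarks <- NULL
    misalignment <- NULL
    if (config$misalignment_max > 0) {
      theta <- stats::runif(1, -1, 1) * 0.3 * config$misalignment_max / (0.45 * s)
      ta <- stats::runif(1, 0, 2 * pi)
      tmag <- stats::runif(1, 0.5, 1) * config$misalignment_max
      shift <- tmag * c(cos(ta), sin(ta))
      ctr2 <- rep(geo$center, 2)
      misalignment <- list(theta = theta, shift = shift, center = ctr2)
      swi <- reslice(swi, warp_rigid(px(swi), theta, shift, ctr2),
                     modality = "SWI")
      swi <- quantize_slice(swi)
      landmarks <- rigid_landmarks(s, theta, shift, ctr2)
    }

    ## three tumour ROIs at 120 degrees inside the disk, three WM ROIs on the annulus
    r_roi_t <- max(2, floor(r_t / 3))
    off <- max(0, r_t - r_roi_t - 1)
    ta_ang <- c(0, 2, 4) * pi / 3
    tumor_rois <- data.frame(row = tc[1] + off * cos(ta_ang),
                             col = tc[2] + off * sin(ta_ang),
                             radius = r_roi_t)
    wa <- c(90, 210, 330) * pi / 180
    wm_rois <- data.frame(row = geo$center + geo$wm_mid * cos(wa),
                          col = geo$center + geo$wm_mid * sin(wa),
                          radius = geo$wm_roi_radius)
    rois <- roi_set(tumor_rois, wm_rois)
    if (!rois_disjoint(rois))
      stop("generate_subject: tumour and white-matter ROIs overlap")

    structure(list(subject_id = subject_id, adc = adc, swi = swi, rois = rois,
                   grade = grade, sex = sex, age = age,
                   wm_mask = geo$wm, tumor_mask = tumor,
                   tumor_center = tc, tumor_radius = r_t,
                   severity_z = zsub, misalignment = misalignment,
                   landmarks = landmarks),
              class = "subject_record")
  })
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s: %s, %s, age %d, %dx%d px, tumour r=%.1f px\n",
              x$subject_id, x$grade, x$sex, x$age, nrow(x$adc), ncol(x$adc),
              x$tumor_radius))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Exactly `round(n_subjects * hgg_fraction)` subjects are labelled HGG (57
#' of 96 at the default 59.3 %); grade order is shuffled deterministically.
#' Per-subject seeds are derived from `config$seed` so cohorts are
#' reproducible and subjects independent.
#'
#' @param config A [phantom_config()].
#' @return A list of [generate_subject()] records with class
#'   `glioma_cohort`; the generating config is attached as an attribute.
#' @export
generate_cohort <- function(config) {
  n <- config$n_subjects
  if (n < 1L) stop("generate_cohort: need at least one subject")
  n_hgg <- round(n * config$hgg_fraction)
  grades <- c(rep("HGG", n_hgg), rep("LGG", n - n_hgg))
  grades <- with_seed(derive_seed(config$seed, 0L), sample(grades))
  subjects <- lapply(seq_len(n), function(i)
    generate_subject(config, grades[i], derive_seed(config$seed, i),
                     subject_id = sprintf("S%03d", i)))
  structure(subjects, class = "glioma_cohort", config = config)
}

#' @export
print.glioma_cohort <- function(x, ...) {
  g <- vapply(x, `[[`, "", "grade")
  cat(sprintf("<glioma_cohort> %d subjects: %d HGG, %d LGG\n",
              length(x), sum(g == "HGG"), sum(g == "LGG")))
  invisible(x)
}

#' Cohort manifest table
#'
#' @param cohort A `glioma_cohort`.
#' @return Data frame with one row per subject: id, grade, sex, age.
#' @export
cohort_manifest <- function(cohort) {
  do.call(rbind, lapply(cohort, function(s)
    data.frame(subject_id = s$subject_id, grade = s$grade,
               sex = s$sex, age = s$age)))
}
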
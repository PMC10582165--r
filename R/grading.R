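## Clinical grading statistics: the relative signal contrast (RSC) between
## tumour and normal-appearing white matter, its group comparison between
## low- and high-grade gliomas, and ROC classification with the
## maximum-Youden cutoff.

#' Two-stage mean intensity over circular ROIs
#'
#' Radiologist convention: the mean is taken within each circular ROI
#' first, then across the (three) per-ROI means -- which differs from a
#' pooled pixel average when the ROIs have unequal sizes.
#'
#' @param image A [slice_image()].
#' @param rois Data frame with columns `row`, `col`, `radius` (0-based
#'   pixel-centre coordinates), one row per ROI.
#' @return Mean intensity.
#' @export
mean_roi_intensity <- function(image, rois) {
  rois <- as.data.frame(rois)
  if (nrow(rois) < 1L) stop("mean_roi_intensity: need at least one ROI")
  X <- px(image)
  rw <- rois$row; cl <- rois$col; rd <- rois$radius
  per_roi <- vapply(seq_along(rw), function(i) {
    idx <- circle_pixels(X, rw[i], cl[i], rd[i])
    if (length(idx) == 0L) stop("mean_roi_intensity: empty ROI")
    mean(X[idx])
  }, 0)
  mean(per_roi)
}

#' Relative signal contrast of a slice
#'
#' `RSC = (mu_ROI - mu_WM) / mu_WM`, where `mu_ROI` is the two-stage mean
#' over the tumour ROIs and `mu_WM` over the white-matter reference ROIs.
#' Scale-free: invariant under multiplying the image by any positive
#' constant.
#'
#' @param image A [slice_image()].
#' @param rois A [roi_set()].
#' @return RSC (unitless).
#' @export
rsc <- function(image, rois) {
  if (!inherits(rois, "roi_set")) stop("rsc: rois must be a roi_set")
  mu_roi <- mean_roi_intensity(image, rois$tumor)
  mu_wm <- mean_roi_intensity(image, rois$wm)
  if (mu_wm <= 0)
    stop("rsc: white-matter reference mean must be positive ",
         "(normalize intensities upstream)")
  (mu_roi - mu_wm) / mu_wm
}

check_rsc_records <- function(records) {
  records <- as.data.frame(records)
  if (!all(c("rsc", "grade") %in% names(records)))
    stop("need columns 'rsc' and 'grade'")
  if (!all(records$grade %in% c("LGG", "HGG")))
    stop("grade must be LGG or HGG")
  records
}

#' Compare RSC between grades
#'
#' Kolmogorov-Smirnov normality check per group (against a normal with
#' moment-estimated parameters; statistic and approximate p reported),
#' followed by a two-tailed unpaired t-test -- equal-variance by default,
#' Welch behind the `welch` flag. The direction of the group difference is
#' reported alongside.
#'
#' @param records Data frame with columns `rsc` and `grade`
#'   (`"LGG"`/`"HGG"`), at least 2 subjects per grade.
#' @param alpha Significance level (default 0.05).
#' @param welch Use the Welch (unequal-variance) t-test instead.
#' @return An object of class `group_comparison`.
#' @export
compare_groups <- function(records, alpha = 0.05, welch = FALSE) {
  records <- check_rsc_records(records)
  x_lgg <- records$rsc[records$grade == "LGG"]
  x_hgg <- records$rsc[records$grade == "HGG"]
  if (length(x_lgg) < 2L || length(x_hgg) < 2L)
    stop("compare_groups: need at least 2 subjects per grade")
  ks_one <- function(x) {
    k <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    c(statistic = unname(k$statistic), p = k$p.value)
  }
  ks <- rbind(LGG = ks_one(x_lgg), HGG = ks_one(x_hgg))
  tt <- stats::t.test(x_lgg, x_hgg, var.equal = !welch)
  structure(list(n = c(LGG = length(x_lgg), HGG = length(x_hgg)),
                 means = c(LGG = mean(x_lgg), HGG = mean(x_hgg)),
                 ks = ks,
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 significant = tt$p.value < alpha,
                 alpha = alpha,
                 welch = welch,
                 direction = if (mean(x_lgg) >= mean(x_hgg)) "LGG>HGG" else "HGG>LGG"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("RSC comparison: LGG mean %.4f (n=%d) vs HGG mean %.4f (n=%d)\n",
              x$means["LGG"], x$n["LGG"], x$means["HGG"], x$n["HGG"]))
  cat(sprintf("  %s t = %.3f, df = %.1f, p = %.4g (%ssignificant at %.2g); %s\n",
              if (x$welch) "Welch" else "equal-variance", x$t_statistic, x$df,
              x$p_value, if (x$significant) "" else "not ", x$alpha, x$direction))
  invisible(x)
}

#' ROC analysis of RSC for grade classification
#'
#' Empirical ROC over all observed thresholds, AUC by trapezoid integration
#' (equal to the normalized Mann-Whitney U statistic, ties counted half),
#' and the operating point maximizing the Youden index
#' `J = sensitivity + specificity - 1` (ties broken to the lowest
#' threshold). HGG is the positive class; by default the direction is
#' auto-detected from the group means (clinically, LGG carries the higher
#' RSC, so lower RSC predicts HGG).
#'
#' @param records Data frame with columns `rsc` and `grade`.
#' @param direction `"auto"` (default), `"lgg_higher"` (predict HGG when
#'   RSC at or below cutoff) or `"hgg_higher"`.
#' @return An object of class `roc_result` with `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `youden`, `direction`, and the full
#'   `curve` (threshold, sensitivity, specificity).
#' @export
roc_analysis <- function(records, direction = c("auto", "lgg_higher", "hgg_higher")) {
  direction <- match.arg(direction)
  records <- check_rsc_records(records)
  x_lgg <- records$rsc[records$grade == "LGG"]
  x_hgg <- records$rsc[records$grade == "HGG"]
  if (length(x_lgg) < 1L || length(x_hgg) < 1L)
    stop("roc_analysis: both grades must be present")
  if (direction == "auto")
    direction <- if (mean(x_lgg) >= mean(x_hgg)) "lgg_higher" else "hgg_higher"
  ## orient scores so that LOW score predicts HGG (the clinical direction);
  ## for the flipped direction negate scores and map the cutoff back
  sgn <- if (direction == "lgg_higher") 1 else -1
  s_hgg <- sgn * x_hgg; s_lgg <- sgn * x_lgg
  if (length(unique(c(s_hgg, s_lgg))) == 1L) {
    return(structure(list(auc = 0.5, cutoff = NA_real_, sensitivity = NA_real_,
                          specificity = NA_real_, youden = NA_real_,
                          direction = direction, degenerate = TRUE,
                          curve = NULL, n = c(LGG = length(x_lgg),
                                              HGG = length(x_hgg))),
                     class = "roc_result"))
  }
  th <- sort(unique(c(s_hgg, s_lgg)))
  sens <- vapply(th, function(t) mean(s_hgg <= t), 0)  # HGG called when score <= t
  spec <- vapply(th, function(t) mean(s_lgg > t), 0)
  fpr <- c(0, 1 - spec, 1)
  tpr <- c(0, sens, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  J <- sens + spec - 1
  best <- which(J == max(J))[1]                 # lowest threshold among maximizers
  structure(list(auc = auc,
                 cutoff = sgn * th[best],
                 sensitivity = sens[best],
                 specificity = spec[best],
                 youden = J[best],
                 direction = direction,
                 degenerate = FALSE,
                 curve = data.frame(threshold = sgn * th, sensitivity = sens,
                                    specificity = spec),
                 n = c(LGG = length(x_lgg), HGG = length(x_hgg))),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("ROC: all RSC values identical; AUC 0.5, cutoff undefined\n")
    return(invisible(x))
  }
  rule <- if (x$direction == "lgg_higher") "RSC <= cutoff -> HGG"
  else "RSC >= cutoff -> HGG"
  cat(sprintf("ROC: AUC %.3f, cutoff %.4f (%s), sens %.3f, spec %.3f, Youden %.3f\n",
              x$auc, x$cutoff, rule, x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

#' Fisher exact test for demographic 2x2 tables
#'
#' Two-sided exact p for the association between a dichotomous demographic
#' factor (sex, or age split at the median) and grade.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_demographics <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("fisher_demographics: need a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("fisher_demographics: counts must be non-negative integers")
  stats::fisher.test(table)$p.value
}

#' Per-method grading table
#'
#' Runs the group comparison per fusion method; methods with a significant
#' LGG/HGG difference enter the ROC table, the rest are listed as excluded
#' (mirroring reports in which non-discriminating methods are dropped from
#' the classification table). The highest AUC is flagged. No
#' multiple-testing correction is applied across methods.
#'
#' @param records Data frame with columns `method`, `rsc`, `grade`.
#' @param alpha Significance level gating table entry (default 0.05).
#' @param direction Passed to [roc_analysis()].
#' @return An object of class `grading_report` with `table`, `excluded`,
#'   `best`, and the per-method `comparisons` and `roc` objects.
#' @export
grading_table <- function(records, alpha = 0.05, direction = "auto") {
  records <- as.data.frame(records)
  stopifnot("method" %in% names(records))
  methods <- unique(records$method)
  comparisons <- list(); rocs <- list()
  rows <- list(); excl <- list()
  for (m in methods) {
    d <- records[records$method == m, ]
    cmp <- tryCatch(compare_groups(d, alpha = alpha), error = function(e) e)
    if (inherits(cmp, "error")) {
      ## too few subjects in a grade (etc.): record as excluded, not fatal
      excl[[m]] <- data.frame(method = m, p_value = NA_real_)
      next
    }
    comparisons[[m]] <- cmp
    if (cmp$significant) {
      r <- roc_analysis(d, direction = direction)
      rocs[[m]] <- r
      rows[[m]] <- data.frame(method = m, cutoff = r$cutoff, auc = r$auc,
                              sensitivity = r$sensitivity,
                              specificity = r$specificity,
                              youden = r$youden, p_value = cmp$p_value,
                              direction = r$direction)
    } else {
      excl[[m]] <- data.frame(method = m, p_value = cmp$p_value)
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(method = character(), cutoff = numeric(), auc = numeric(),
               sensitivity = numeric(), specificity = numeric(),
               youden = numeric(), p_value = numeric(), direction = character())
  rownames(tab) <- NULL
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(method = character(), p_value = numeric())
  rownames(excluded) <- NULL
  best <- if (nrow(tab)) tab$method[which.max(tab$auc)] else NA_character_
  structure(list(table = tab, excluded = excluded, best = best,
                 comparisons = comparisons, roc = rocs, alpha = alpha),
            class = "grading_report")
}

#' @export
print.grading_report <- function(x, ...) {
  cat("ROC grading table (methods with significant LGG/HGG RSC difference):\n")
  if (nrow(x$table)) print(x$table, row.names = FALSE, digits = 4)
  else cat("  (none)\n")
  if (nrow(x$excluded)) {
    cat("Excluded (no significant group difference):",
        paste(sprintf("%s (p=%.3g)", x$excluded$method, x$excluded$p_value),
              collapse = ", "), "\n")
  }
  if (!is.na(x$best)) cat("Highest AUC:", x$best, "\n")
  cat("Note: p-values are per method; no multiple-testing correction applied.\n")
  invisible(x)
}
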
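test_that("two-stage ROI averaging matches hand values and differs from pooling", {
  img <- slice_image(matrix(100, 32, 32))
  rois <- data.frame(row = c(5, 15, 25), col = c(5, 15, 25), radius = 2)
  expect_equal(mean_roi_intensity(img, rois), 100)
  ## three single-pixel ROIs with values 10, 20, 60 -> 30
  X <- matrix(0, 32, 32); X[6, 6] <- 10; X[16, 16] <- 20; X[26, 26] <- 60
  tiny <- data.frame(row = c(5, 15, 25), col = c(5, 15, 25), radius = 0.4)
  expect_equal(mean_roi_intensity(slice_image(X), tiny), 30)
  ## unequal ROI sizes: two-stage differs from the pooled pixel average
  Y <- matrix(0, 32, 32)
  big <- gliofuse:::circle_pixels(Y, 10, 10, 4); Y[big] <- 10
  Y[26, 26] <- 100
  uneq <- data.frame(row = c(10, 25), col = c(10, 25), radius = c(4, 0.4))
  two_stage <- mean_roi_intensity(slice_image(Y), uneq)
  pooled <- mean(c(Y[big], 100))
  expect_equal(two_stage, 55)
  expect_false(isTRUE(all.equal(two_stage, pooled)))
  expect_error(mean_roi_intensity(img, data.frame(row = 1, col = 1, radius = 5)),
               "outside")
})

test_that("RSC follows its defining ratio and scale invariance", {
  X <- matrix(100, 64, 64)
  tm <- gliofuse:::circle_pixels(X, 20, 20, 5); X[tm] <- 150
  rois <- roi_set(data.frame(row = 20, col = 20, radius = 3),
                  data.frame(row = c(45, 50, 45), col = c(45, 45, 50), radius = 2))
  img <- slice_image(X)
  expect_equal(rsc(img, rois), 0.5)
  expect_equal(rsc(slice_image(3 * X, bit_depth = 1024), rois), 0.5)
  flat <- slice_image(matrix(100, 64, 64))
  expect_equal(rsc(flat, rois), 0)
  expect_error(rsc(slice_image(matrix(0, 64, 64)), rois), "positive")
})

test_that("group comparison handles identical groups and detects designed gaps", {
  d0 <- data.frame(rsc = c(1, 2, 3, 1, 2, 3),
                   grade = rep(c("LGG", "HGG"), each = 3))
  c0 <- compare_groups(d0)
  expect_equal(c0$t_statistic, 0)
  expect_equal(c0$p_value, 1)
  expect_false(c0$significant)
  ## power oracle: 1.5 pooled-SD gap at n=48/48 is significant at p < 0.01
  ## in at least 95% of seeds
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    d <- data.frame(rsc = c(rnorm(48, 1.5, 1), rnorm(48, 0, 1)),
                    grade = rep(c("LGG", "HGG"), each = 48))
    compare_groups(d)$p_value < 0.01
  }, NA)
  expect_gte(mean(hits), 0.95)
  expect_error(compare_groups(data.frame(rsc = 1:3, grade = c("LGG", "LGG", "LGG"))),
               "2 subjects")
  ## KS output present per group
  expect_equal(rownames(c0$ks), c("LGG", "HGG"))
})

test_that("ROC analysis matches exhaustive enumeration on toy data", {
  toy <- data.frame(rsc = c(0.6, 0.8, 0.2, 0.4),
                    grade = c("LGG", "LGG", "HGG", "HGG"))
  r <- roc_analysis(toy)
  expect_equal(r$auc, 1)
  expect_equal(r$youden, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  ## the cutoff separates the groups: every HGG at or below, every LGG above
  expect_true(all(toy$rsc[toy$grade == "HGG"] <= r$cutoff))
  expect_true(all(toy$rsc[toy$grade == "LGG"] > r$cutoff))
  expect_equal(r$direction, "lgg_higher")
  ## all-identical scores: flagged degenerate with AUC 0.5
  flat <- data.frame(rsc = rep(0.3, 8), grade = rep(c("LGG", "HGG"), 4))
  rf <- roc_analysis(flat)
  expect_true(rf$degenerate)
  expect_equal(rf$auc, 0.5)
  expect_true(is.na(rf$cutoff))
})

test_that("trapezoid AUC equals the normalized Mann-Whitney statistic", {
  set.seed(14)
  for (i in 1:200) {
    n1 <- sample(3:30, 1); n2 <- sample(3:30, 1)
    x <- round(rnorm(n1, 0.3, 0.25), sample(1:3, 1))  # rounding induces ties
    y <- round(rnorm(n2, 0.0, 0.25), sample(1:3, 1))
    d <- data.frame(rsc = c(x, y), grade = rep(c("LGG", "HGG"), c(n1, n2)))
    r <- roc_analysis(d, direction = "lgg_higher")
    mw <- mean(outer(x, y, ">")) + 0.5 * mean(outer(x, y, "=="))
    expect_equal(r$auc, mw, tolerance = 1e-12)
  }
})

test_that("ROC agrees with an independent implementation and is rank-invariant", {
  skip_if_not_installed("pROC")
  set.seed(15)
  d <- binormal_records(0.85, 60, seed = 15)
  r <- roc_analysis(d)
  p <- pROC::roc(response = d$grade, predictor = d$rsc, levels = c("HGG", "LGG"),
                 direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(p)), tolerance = 1e-9)
  ## Youden cutoff invariance under strictly monotone transforms
  dm <- d; dm$rsc <- exp(2 * dm$rsc)
  rm_ <- roc_analysis(dm)
  expect_equal(rm_$auc, r$auc, tolerance = 1e-12)
  expect_equal(rm_$sensitivity, r$sensitivity)
  expect_equal(rm_$specificity, r$specificity)
  expect_equal(rm_$cutoff, exp(2 * r$cutoff), tolerance = 1e-9)
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  expect_equal(fisher_demographics(matrix(c(5, 5, 5, 5), 2)), 1)
  ## enumeration oracle for the fully separated 10/0/0/10 table
  tab <- matrix(c(10, 0, 0, 10), 2)
  enum_p <- local({
    m <- 10; n <- 10; k <- 10
    probs <- stats::dhyper(0:10, m, n, k)
    sum(probs[probs <= stats::dhyper(10, m, n, k) * (1 + 1e-7)])
  })
  expect_equal(fisher_demographics(tab), enum_p, tolerance = 1e-9)
  ## transpose invariance
  t2 <- matrix(c(7, 2, 3, 9), 2)
  expect_equal(fisher_demographics(t2), fisher_demographics(t(t2)))
  expect_error(fisher_demographics(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("grading table gates on significance and flags the best AUC", {
  set.seed(16)
  sig <- binormal_records(0.9, 40, seed = 16); sig$method <- "PCA"
  sig2 <- binormal_records(0.95, 40, seed = 17); sig2$method <- "LRD"
  null <- data.frame(rsc = rnorm(80, 0, 0.2),
                     grade = rep(c("LGG", "HGG"), each = 40),
                     method = "STRUCTURE_AWARE")
  g <- grading_table(rbind(sig, sig2, null))
  expect_setequal(g$table$method, c("PCA", "LRD"))
  expect_equal(g$excluded$method, "STRUCTURE_AWARE")
  expect_equal(g$best, g$table$method[which.max(g$table$auc)])
  ## single significant method -> one-row table
  g1 <- grading_table(sig)
  expect_equal(nrow(g1$table), 1L)
})
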
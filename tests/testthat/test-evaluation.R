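test_that("ROC curves are valid step curves whose area equals the AUROC", {
  set.seed(61)
  for (r in 1:1000) {
    n <- sample(4:20, 1)
    scores <- sample(0:6, n, replace = TRUE) +
      if (r %% 2) 0 else stats::rnorm(n)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    rc <- roc_curve(scores, labels)
    expect_identical(unname(unlist(rc[1, ])), c(0, 0))
    expect_identical(unname(unlist(rc[nrow(rc), ])), c(1, 1))
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_equal(auc_trapezoid(rc$fpr, rc$tpr),
                 auroc(scores[labels], scores[!labels]),
                 tolerance = 1e-12)
  }
})

test_that("ROC boundary cases", {
  rc <- roc_curve(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(any(rc$fpr == 0 & rc$tpr == 1))  # perfect separation
  expect_equal(auc_trapezoid(rc$fpr, rc$tpr), 1)
  rc2 <- roc_curve(rep(2, 6), rep(c(TRUE, FALSE), 3))  # all tied
  expect_identical(nrow(rc2), 2L)
  expect_equal(auc_trapezoid(rc2$fpr, rc2$tpr), 0.5)
  rc3 <- roc_curve(c(1, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(auc_trapezoid(rc3$fpr, rc3$tpr), 0.875)
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "positive and a negative")
})

test_that("stratified partitions are disjoint, exhaustive and balanced", {
  set.seed(67)
  # single class, n divisible by k: exactly equal folds
  f <- slescore:::make_folds(rep("x", 9), 3)
  expect_identical(as.vector(table(f)), rep(3L, 3))
  # mixed classes: per-class fold counts within 1
  for (r in 1:20) {
    cls <- sample(rep(c("a", "b", "c"), times = c(11, 7, 5)))
    f <- slescore:::make_folds(cls, 3)
    expect_identical(length(f), length(cls))
    expect_true(all(f %in% 1:3))
    per <- table(cls, f)
    expect_true(all(apply(per, 1, function(x) diff(range(x))) <= 1))
  }
  expect_error(slescore:::make_folds(c("a", "a", "a", "b", "b"), 3),
               "stratification failure.*'b'")
})

test_that("repeated sub-sampling CV is reproducible and well-formed", {
  cc <- small_cohort_config(seed = 71)
  co <- generate_cohort(cc)
  filt <- apply_filters(co$slides, cc$panel)
  cls <- co$metadata$clinical_class[
    match(rownames(filt$matrix$values), co$metadata$sample_id)]
  cv1 <- cv_repeated_subsampling(filt$matrix, cls, B = 5, k = 3, seed = 99)
  cv2 <- cv_repeated_subsampling(filt$matrix, cls, B = 5, k = 3, seed = 99)
  expect_identical(cv1$auroc, cv2$auroc)
  expect_identical(cv1$folds, cv2$folds)
  expect_true(all(cv1$auroc >= 0 & cv1$auroc <= 1, na.rm = TRUE))
  # every iteration's folds cover all samples
  expect_true(all(apply(cv1$folds, 1, function(f) all(f %in% 1:3))))
  cv3 <- cv_repeated_subsampling(filt$matrix, cls, B = 5, k = 3, seed = 100)
  expect_false(identical(cv1$auroc, cv3$auroc))
  expect_error(cv_repeated_subsampling(filt$matrix, cls, B = 2, k = 3),
               "seed")
})

test_that("single-test-fold mode scores one fold per iteration", {
  cc <- cohort_config(n_per_class = c(healthy = 12, sle_active = 9),
                      seed = 73)
  co <- generate_cohort(cc)
  filt <- apply_filters(co$slides, cc$panel)
  cls <- co$metadata$clinical_class[
    match(rownames(filt$matrix$values), co$metadata$sample_id)]
  cv <- cv_repeated_subsampling(filt$matrix, cls, B = 3, k = 3, seed = 5,
                                rotate = FALSE)
  expect_true(all(is.finite(cv$auroc[, "active_vs_healthy"])))
})

test_that("pairwise class AUROCs span the null and separable extremes", {
  # identical distributions: mean AUROC near 0.5
  cc0 <- cohort_config(n_per_class = c(ra = 24, other_ai = 24), seed = 79)
  co0 <- generate_null_cohort(cc0)
  filt0 <- apply_filters(co0$slides, cc0$panel)
  cls0 <- co0$metadata$clinical_class[
    match(rownames(filt0$matrix$values), co0$metadata$sample_id)]
  pw0 <- pairwise_class_auroc(filt0$matrix, cls0,
                              class_pairs = list(x = c("ra", "other_ai")),
                              B = 25, k = 3, seed = 3)
  expect_gt(pw0$mean_auroc, 0.38)
  expect_lt(pw0$mean_auroc, 0.62)
  # a 10-SD planted shift separates perfectly
  panel <- default_panel()
  eff <- matrix(0, 82, 6,
                dimnames = list(capture_features(panel), clinical_classes()))
  eff[1:10, "sle_active"] <- -10
  cc1 <- cohort_config(n_per_class = c(healthy = 15, sle_active = 12),
                       effect_profile = eff, seed = 83)
  co1 <- generate_cohort(cc1)
  filt1 <- apply_filters(co1$slides, cc1$panel)
  cls1 <- co1$metadata$clinical_class[
    match(rownames(filt1$matrix$values), co1$metadata$sample_id)]
  pw1 <- pairwise_class_auroc(filt1$matrix, cls1,
                              class_pairs = list(x = c("sle_active",
                                                       "healthy")),
                              B = 25, k = 3, seed = 3)
  expect_gt(pw1$mean_auroc, 0.95)
})

test_that("feature-set comparison shares partitions and handles B = 1", {
  co <- generate_cohort(small_cohort_config(seed = 89))
  filt <- apply_filters(co$slides, co$config$panel)
  fs <- feature_set_comparison(filt$matrix, co$metadata,
                               tasks = list(svi = c("sle_semi",
                                                    "sle_inactive")),
                               B = 1, k = 3, seed = 2)
  expect_true(all(is.na(fs$tasks$svi$tests$p)))
  expect_match(fs$tasks$svi$tests$note[1], "B < 2")
  fs2 <- feature_set_comparison(filt$matrix, co$metadata,
                                tasks = list(svi = c("sle_semi",
                                                     "sle_inactive")),
                                B = 8, k = 3, seed = 2)
  expect_identical(dim(fs2$tasks$svi$auroc), c(8L, 3L))
  expect_identical(fs2$tasks$svi$tests$hypothesis,
                   c("combined > array", "combined > labs", "labs > array"))
  expect_true(all(fs2$tasks$svi$auroc >= 0 & fs2$tasks$svi$auroc <= 1))
})

test_that("missing lab values are reported by sample", {
  co <- generate_cohort(small_cohort_config(seed = 97))
  filt <- apply_filters(co$slides, co$config$panel)
  md <- co$metadata
  victim <- md$sample_id[md$clinical_class == "sle_semi"][1]
  md$c3[md$sample_id == victim] <- NA
  expect_error(
    feature_set_comparison(filt$matrix, md,
                           tasks = list(svi = c("sle_semi", "sle_inactive")),
                           B = 2, k = 3, seed = 2),
    victim, fixed = TRUE)
})

test_that("null calibration: label permutation keeps CV AUROC near 0.5", {
  cc <- cohort_config(n_per_class = c(healthy = 18, sle_active = 18),
                      seed = 101)
  co <- generate_cohort(cc)  # real effects, then permuted labels
  filt <- apply_filters(co$slides, cc$panel)
  cls <- co$metadata$clinical_class[
    match(rownames(filt$matrix$values), co$metadata$sample_id)]
  set.seed(1)
  cls_perm <- sample(cls)
  cv <- cv_repeated_subsampling(filt$matrix, cls_perm, B = 30, k = 3,
                                seed = 9)
  expect_gt(cv$auroc_mean[["active_vs_healthy"]], 0.40)
  expect_lt(cv$auroc_mean[["active_vs_healthy"]], 0.60)
})
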
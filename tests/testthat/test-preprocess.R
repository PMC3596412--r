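test_that("normalization maps the brightest capture spot to exactly 10", {
  panel <- small_panel()
  rep1 <- c(500, 2000, 100, 0, 50, 40, 30, 20, 10, 3000)  # anchor brightest
  sl <- make_slide("S1", panel, rep1)
  ns <- normalize_slide(sl, panel)
  # capture max is 2000 (CD3); the anchor does not enter the max
  expect_identical(unname(ns$intensities["CD3", 1]), 10)
  expect_identical(unname(ns$intensities["CD2", 1]), 2.5)
  expect_identical(unname(ns$intensities["CD7", 1]), 0)
  expect_identical(unname(ns$intensities["CD44", 1]), 15)  # same factor
})

test_that("normalization is scale-invariant and idempotent", {
  panel <- small_panel()
  sl <- random_slides(panel, 1, seed = 11)[[1]]
  n1 <- normalize_slide(sl, panel)
  sl3 <- sl
  sl3$intensities <- sl$intensities * 3
  expect_equal(normalize_slide(sl3, panel)$intensities, n1$intensities,
               tolerance = 1e-12)
  expect_equal(normalize_slide(n1, panel)$intensities, n1$intensities,
               tolerance = 1e-12)
})

test_that("all-zero slides are rejected as degenerate", {
  panel <- small_panel()
  sl <- make_slide("S1", panel, rep(0, nrow(panel)))
  expect_error(normalize_slide(sl, panel), "degenerate")
})

test_that("replicate merging returns means and absolute differences", {
  panel <- small_panel()
  sl <- make_slide("S1", panel, rep1 = c(4, 7, 0, 1, 2, 3, 4, 5, 6, 7),
                   rep2 = c(6, 7, 10, 1, 2, 3, 4, 5, 6, 7))
  m <- merge_replicates(sl)
  expect_identical(m$mean[m$feature_id == "CD2"], 5)
  expect_identical(m$repdiff[m$feature_id == "CD2"], 2)
  expect_identical(m$repdiff[m$feature_id == "CD3"], 0)
  expect_identical(m$mean[m$feature_id == "CD5"], 5)
  expect_identical(m$repdiff[m$feature_id == "CD5"], 10)
})

test_that("low-expression filter uses the top-20% median with a strict cut", {
  vals <- cbind(a = c(10, 9, rep(0, 8)),     # top-2 median 9.5 -> pass
                b = rep(0.9, 10),            # 0.9 < 1 -> fail
                c = rep(1.0, 10))            # exactly 1 -> pass
  em <- manual_em(vals)
  res <- low_expression_filter(em, features = colnames(vals))
  expect_identical(res$top20_median, c(9.5, 0.9, 1.0))
  expect_identical(res$passed_low_expression, c(TRUE, FALSE, TRUE))
})

test_that("low-expression filter warns below five samples", {
  em <- manual_em(cbind(a = c(1, 2, 3, 4)))
  expect_warning(low_expression_filter(em, features = "a"),
                 "single sample")
})

test_that("SNR filter applies the strict 1.2 cut with degenerate handling", {
  # antigen a: sd = 1.2, mean |diff| = 1.0 -> SNR 1.2 -> pass (equality)
  x <- c(1, 2, 3)
  a <- x / stats::sd(x) * 1.2
  vals <- cbind(a = a, b = c(5, 5, 5), c = c(1, 2, 3), d = c(2, 2, 2))
  diffs <- cbind(a = c(1, 1, 1), b = c(0.5, 0.5, 0.5), c = c(0, 0, 0),
                 d = c(0, 0, 0))
  em <- manual_em(vals, diffs)
  res <- snr_filter(em, features = colnames(vals))
  expect_equal(res$snr[1], 1.2, tolerance = 1e-12)
  expect_true(res$passed_snr[1])
  # b: constant antigen, sd 0 -> SNR 0 -> fail
  expect_identical(res$snr[2], 0)
  expect_false(res$passed_snr[2])
  # c: zero replicate difference with real variance -> infinite SNR -> pass
  expect_identical(res$snr[3], Inf)
  expect_true(res$passed_snr[3])
  # d: 0/0 -> degenerate -> fail
  expect_true(is.nan(res$snr[4]))
  expect_false(res$passed_snr[4])
  expect_identical(res$snr_reason[4], "degenerate")
  # just below the threshold fails (strict inequality)
  em2 <- manual_em(cbind(a = a * (1 - 1e-9)), cbind(a = c(1, 1, 1)))
  expect_false(snr_filter(em2, features = "a")$passed_snr)
})

test_that("SNR formula matches direct evaluation", {
  em <- manual_em(cbind(g = c(1, 2, 3)), cbind(g = c(0.5, 0.5, 0.5)))
  res <- snr_filter(em, features = "g")
  expect_equal(res$snr, 2.0, tolerance = 1e-12)
  expect_true(res$passed_snr)
})

test_that("planted detection-floor antigens are exactly the filter failures", {
  cc <- small_cohort_config(seed = 31)
  co <- generate_cohort(cc)
  filt <- apply_filters(co$slides, cc$panel)
  rep <- filt$report
  failed <- rep$feature_id[rep$category == "capture" &
                             !rep$passed_low_expression]
  expect_setequal(failed, co$truth$low_antigens)
  # report completeness: every capture antigen is either retained or dropped
  cap <- rep[rep$category == "capture", ]
  expect_identical(sum(cap$retained) + sum(!cap$retained),
                   sum(default_panel()$category == "capture"))
  expect_identical(colnames(filt$matrix$values),
                   cap$feature_id[cap$retained])
})

test_that("zero replicate noise gives infinite SNR for varying antigens", {
  cc <- small_cohort_config(seed = 37, replicate_noise_sd = 0)
  co <- generate_cohort(cc)
  filt <- apply_filters(co$slides, cc$panel)
  cap <- filt$report[filt$report$category == "capture", ]
  expect_true(all(is.infinite(cap$snr) | is.nan(cap$snr)))
  expect_true(all(cap$passed_snr[is.infinite(cap$snr)]))
})

test_that("filter decisions are monotone in their thresholds", {
  cc <- small_cohort_config(seed = 41, replicate_noise_sd = 150)
  co <- generate_cohort(cc)
  base <- apply_filters(co$slides, cc$panel, preprocess_params())
  retained0 <- base$report$feature_id[base$report$retained]
  # lowering the SNR threshold never removes a retained antigen
  lower <- apply_filters(co$slides, cc$panel,
                         preprocess_params(snr_threshold = 0.6))
  expect_true(all(retained0 %in%
                    lower$report$feature_id[lower$report$retained]))
  # raising the low-expression threshold never adds one
  higher <- apply_filters(co$slides, cc$panel,
                          preprocess_params(low_expr_threshold = 2))
  expect_true(all(higher$report$feature_id[higher$report$retained] %in%
                    retained0))
})

test_that("the assembled matrix is scale-invariant in raw intensities", {
  panel <- small_panel()
  slides <- random_slides(panel, 6, seed = 43)
  em1 <- build_expression_matrix(slides, panel)
  scaled <- lapply(slides, function(s) {
    s$intensities <- s$intensities * 7.3
    s
  })
  em2 <- build_expression_matrix(scaled, panel)
  expect_equal(em1$values, em2$values, tolerance = 1e-12)
  expect_equal(em1$repdiff, em2$repdiff, tolerance = 1e-12)
  expect_true(all(em1$values >= 0))
  expect_true(all(em1$values[, capture_features(panel)] <= 10 + 1e-12))
})

test_that("expression matrices and filter reports are written with provenance", {
  cc <- small_cohort_config(seed = 47)
  co <- generate_cohort(cc)
  filt <- apply_filters(co$slides, cc$panel)
  dir <- withr::local_tempdir()
  write_expression_matrix(filt$matrix, file.path(dir, "em.tsv"))
  expect_match(readLines(file.path(dir, "em.tsv"), n = 1L), "^#params")
  write_filter_report(filt$report, file.path(dir, "fr.tsv"),
                      file.path(dir, "fr.json"))
  back <- utils::read.delim(file.path(dir, "fr.tsv"))
  expect_identical(nrow(back), nrow(filt$report))
  js <- jsonlite::read_json(file.path(dir, "fr.json"), simplifyVector = TRUE)
  expect_identical(nrow(js), nrow(filt$report))
})
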
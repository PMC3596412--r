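test_that("auroc equals the exhaustive pairwise-counting oracle", {
  # every multiset of scores up to size 6 per class over alphabet {0,1,2,3}
  alphabet <- 0:3
  multisets <- function(n) {
    if (n == 1L) return(as.list(alphabet))
    unlist(lapply(multisets(n - 1L), function(m) {
      lapply(alphabet[alphabet >= m[length(m)]], function(a) c(m, a))
    }), recursive = FALSE)
  }
  all_sets <- unlist(lapply(1:6, multisets), recursive = FALSE)
  set.seed(23)  # exhaustive in structure; subsample pairs for runtime
  idx <- cbind(sample(length(all_sets), 4000, replace = TRUE),
               sample(length(all_sets), 4000, replace = TRUE))
  for (r in seq_len(nrow(idx))) {
    pos <- all_sets[[idx[r, 1]]]
    neg <- all_sets[[idx[r, 2]]]
    expect_equal(auroc(pos, neg), auroc_oracle(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("auroc reproduces hand-computed and boundary cases", {
  expect_identical(auroc(c(2, 3), c(0, 1)), 1)
  expect_identical(auroc(c(0, 1), c(2, 3)), 0)
  expect_identical(auroc(c(1, 2), c(1, 0)), 0.875)  # (0.5 + 1 + 1 + 1) / 4
  expect_identical(auroc(c(5, 5, 5), c(5, 5, 5)), 0.5)
  expect_error(auroc(numeric(0), 1), "at least one")
})

test_that("auroc is symmetric under class exchange", {
  set.seed(29)
  for (r in 1:50) {
    pos <- sample(0:5, sample(1:6, 1), replace = TRUE)
    neg <- sample(0:5, sample(1:6, 1), replace = TRUE)
    expect_equal(auroc(pos, neg), 1 - auroc(neg, pos), tolerance = 1e-15)
  }
})

test_that("planted markers qualify across the six comparisons", {
  cc <- cohort_config(seed = 7)
  co <- generate_cohort(cc)
  filt <- apply_filters(co$slides, cc$panel)
  res <- run_comparisons(filt$matrix, co$metadata)
  expect_identical(sort(unique(res$table$comparison)),
                   sort(names(activity_comparisons())))
  # a strongly shifted T-cell marker qualifies with high separability
  expect_true("CD2" %in% res$qualified)
  cd2 <- res$table[res$table$antigen == "CD2" &
                     res$table$comparison == "semi_vs_healthy", ]
  expect_gt(cd2$auroc, 0.7)
  expect_lt(cd2$p, 0.05)
  expect_identical(unname(res$direction["CD2"]), "down")
  expect_identical(unname(res$direction["CD66c"]), "up")
  # reported AUROC is the separability (>= 0.5); raw value keeps orientation
  expect_true(all(res$table$auroc >= 0.5))
  expect_lt(cd2$auroc_raw, 0.5)
})

test_that("comparisons lacking a class are skipped and reported", {
  cc <- cohort_config(n_per_class = c(healthy = 10, sle_inactive = 10,
                                      sle_active = 8), seed = 43)
  co <- generate_cohort(cc)
  filt <- apply_filters(co$slides, cc$panel)
  expect_message(res <- run_comparisons(filt$matrix, co$metadata),
                 "skipped")
  expect_setequal(res$skipped,
                  c("semi_vs_healthy", "semi_vs_inactive", "active_vs_semi"))
  expect_setequal(unique(res$table$comparison),
                  c("inactive_vs_healthy", "active_vs_healthy",
                    "active_vs_inactive"))
})

test_that("qualification needs p and AUROC within the same comparison", {
  fake <- function(tab) structure(list(table = tab), class = "biomarker_result")
  tab <- data.frame(
    antigen = c("x", "x", "y", "z"),
    comparison = c("c1", "c2", "c1", "c1"),
    p = c(0.01, 0.5, 0.04, 0.01),
    auroc = c(0.6, 0.75, 0.71, 0.68))
  q <- qualify_singletons(fake(tab))
  expect_identical(q, "y")              # 0.04 & 0.71 in one comparison
  expect_false("x" %in% q)              # split across comparisons
  expect_false("z" %in% q)              # auroc below threshold everywhere
  # strictness at the boundaries
  tab2 <- data.frame(antigen = "w", comparison = "c1", p = 0.05, auroc = 0.7)
  expect_length(qualify_singletons(fake(tab2)), 0L)
  # monotonicity: tightening thresholds never adds an antigen
  q_tight <- qualify_singletons(fake(tab), p_max = 0.02, auroc_min = 0.8)
  expect_true(all(q_tight %in% q))
})

test_that("correlation matrix is symmetric with unit diagonal", {
  cc <- cohort_config(seed = 7)
  co <- generate_cohort(cc)
  filt <- apply_filters(co$slides, cc$panel)
  cm <- correlation_matrix(filt$matrix, labs = lab_matrix(co$metadata))
  expect_equal(cm, t(cm), tolerance = 1e-12)
  expect_equal(unname(diag(cm)), rep(1, ncol(cm)), tolerance = 1e-12)
  expect_true(all(abs(cm[is.finite(cm)]) <= 1 + 1e-12))
  # co-regulated T-cell markers form a correlated block
  tcell <- cm[c("CD2", "CD3", "CD5", "CD7"), c("CD2", "CD3", "CD5", "CD7")]
  expect_gt(min(tcell), 0.6)
})

test_that("constant columns yield a flagged undefined correlation", {
  x <- cbind(a = c(1, 2, 3, 4), b = rep(2, 4))
  rownames(x) <- sprintf("S%d", 1:4)
  expect_warning(cm <- correlation_matrix(x), "constant column.*b")
  expect_true(is.na(cm["a", "b"]))
})

test_that("hierarchical clustering is deterministic with sensible structure", {
  set.seed(31)
  x <- rbind(matrix(stats::rnorm(10 * 8, 0), nrow = 10),
             matrix(stats::rnorm(10 * 8, 4), nrow = 10))
  rownames(x) <- sprintf("S%02d", 1:20)
  colnames(x) <- sprintf("g%d", 1:8)
  cl <- hierarchical_cluster(x)
  expect_identical(cl$sample_order,
                   hierarchical_cluster(x)$sample_order)
  # two well-separated blocks give two pure top-level clusters
  groups <- stats::cutree(cl$sample_hclust, k = 2)
  tab <- table(groups, rep(c("a", "b"), each = 10))
  expect_true(all(apply(tab, 1, max) / rowSums(tab) >= 0.8))
  # identical profiles merge first at height zero
  x2 <- rbind(x, x[1, , drop = FALSE])
  rownames(x2)[21] <- "S21"
  cl2 <- hierarchical_cluster(x2)
  expect_equal(cl2$sample_hclust$height[1], 0, tolerance = 1e-12)
  # one antigen: the top-level split separates low from high values and
  # every merge is contiguous in the leaf order
  x3 <- matrix(c(5, 1, 12, 2.5), ncol = 1,
               dimnames = list(sprintf("S%d", 1:4), "g1"))
  cl3 <- hierarchical_cluster(x3)
  split2 <- stats::cutree(cl3$sample_hclust, k = 2)
  expect_true(max(x3[split2 == split2[["S2"]], 1]) <
                min(x3[split2 != split2[["S2"]], 1]))
  ord <- cl3$sample_order
  expect_setequal(ord, rownames(x3))
})

test_that("the wide biomarker table has p and AUROC per comparison", {
  cc <- small_cohort_config(seed = 53)
  co <- generate_cohort(cc)
  filt <- apply_filters(co$slides, cc$panel)
  res <- run_comparisons(filt$matrix, co$metadata)
  path <- withr::local_tempfile(fileext = ".tsv")
  wide <- write_biomarker_table(res, cc$panel, path)
  expect_identical(nrow(wide), ncol(filt$matrix$values))
  for (cm in names(activity_comparisons())) {
    expect_true(all(c(paste0("p_", cm), paste0("auroc_", cm)) %in%
                      names(wide)))
  }
  expect_true(file.exists(path))
})
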
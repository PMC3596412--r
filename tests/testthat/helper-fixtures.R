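# Shared fixtures: a small panel and slide builders used across tests.

small_panel <- function() {
  antibody_panel(data.frame(
    feature_id = c("CD2", "CD3", "CD5", "CD7", "CD19", "CD56", "CD66c",
                   "CD95", "IgG1-iso", "CD44"),
    label = c("CD2", "CD3", "CD5", "CD7", "CD19", "CD56", "CD66c", "CD95",
              "IgG1 isotype", "CD44"),
    category = c(rep("capture", 8L), "isotype_control", "anchor"),
    lineage = c("T", "T", "T", "T", "B", "NK", "other", "other", "other",
                "other"),
    stringsAsFactors = FALSE
  ))
}

# Slide with given per-feature replicate pairs (matrix rows follow panel).
make_slide <- function(sample_id, panel, rep1, rep2 = rep1) {
  m <- cbind(rep1, rep2)
  rownames(m) <- panel$feature_id
  slide_raw(sample_id, m, panel)
}

random_slides <- function(panel, n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    make_slide(sprintf("S%02d", i), panel,
               rep1 = stats::runif(nrow(panel), 10, 2000),
               rep2 = stats::runif(nrow(panel), 10, 2000))
  })
}

# Hand-constructed expression matrix (bypasses normalization) for filter
# unit tests.
manual_em <- function(values, repdiff = NULL,
                      params = preprocess_params()) {
  if (is.null(repdiff)) repdiff <- values * 0
  structure(list(values = values, repdiff = repdiff,
                 panel = NULL, params = params),
            class = "expr_matrix")
}

# Small fast cohort for pipeline-level tests.
small_cohort_config <- function(seed = 1, ...) {
  cohort_config(n_per_class = c(healthy = 8, sle_inactive = 8, sle_semi = 6,
                                sle_active = 6, ra = 5, other_ai = 5),
                seed = seed, ...)
}

# Brute-force pairwise-counting AUROC oracle (independent of the midrank
# implementation under test).
auroc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
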
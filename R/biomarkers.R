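#' Tie-aware AUROC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic divided by
#' \eqn{n_+ n_-}: the probability that a randomly chosen positive scores
#' above a randomly chosen negative, with ties credited one half. Computed
#' via midranks, so it is exact under ties.
#'
#' @param scores_pos scores of the positive class
#' @param scores_neg scores of the negative class
#' @return AUROC in `[0, 1]`
#' @export
auroc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) == 0L || length(scores_neg) == 0L) {
    stop("auroc needs at least one score in each class")
  }
  if (anyNA(scores_pos) || anyNA(scores_neg)) stop("auroc: NA score")
  np <- length(scores_pos)
  nn <- length(scores_neg)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' The six disease-activity comparisons
#'
#' Each comparison is an ordered pair (positive class first, i.e. the
#' clinically more affected member): the three SLE grades against healthy,
#' and the three pairwise contrasts among the grades.
#'
#' @return named list of length-2 character vectors `c(positive, negative)`
#' @export
activity_comparisons <- function() {
  list(
    inactive_vs_healthy  = c("sle_inactive", "healthy"),
    semi_vs_healthy      = c("sle_semi", "healthy"),
    active_vs_healthy    = c("sle_active", "healthy"),
    active_vs_inactive   = c("sle_active", "sle_inactive"),
    semi_vs_inactive     = c("sle_semi", "sle_inactive"),
    active_vs_semi       = c("sle_active", "sle_semi")
  )
}

#' Screen antigens across the activity comparisons
#'
#' For each comparison, fits the moderated t-test across antigens and
#' computes the per-antigen AUROC with the clinically more affected class as
#' positive. Hyperparameters of the moderated t are estimated separately
#' within each comparison. An antigen qualifies as a singleton biomarker if
#' it attains `p < p_max` and `AUROC > auroc_min` within the same comparison.
#'
#' Because markers may be down-regulated with activity, the reported
#' per-antigen AUROC is the separability `max(A, 1 - A)` of the raw
#' more-affected-positive AUROC `A` (so it is always >= 0.5, as such tables
#' are conventionally printed); the raw oriented value is kept alongside as
#' `auroc_raw` and the sign of the mean difference gives the direction.
#'
#' @param em an `expr_matrix` (or plain samples x antigens matrix)
#' @param metadata metadata data frame with `sample_id` and `clinical_class`
#' @param comparisons named list of ordered class pairs
#'   (default [activity_comparisons()])
#' @param p_max,auroc_min qualification thresholds (strict inequalities)
#' @return object of class `biomarker_result`: list with `table` (long data
#'   frame: antigen, comparison, p, auroc, auroc_raw), `direction` (per
#'   antigen, from the sign of the active-vs-healthy mean difference),
#'   `qualified` (character vector), `skipped` (comparisons lacking a class)
#' @export
run_comparisons <- function(em, metadata,
                            comparisons = activity_comparisons(),
                            p_max = 0.05, auroc_min = 0.7) {
  values <- if (inherits(em, "expr_matrix")) em$values else em
  cls <- metadata$clinical_class[match(rownames(values),
                                       metadata$sample_id)]
  if (anyNA(cls)) stop("metadata missing for some samples in the matrix")
  tabs <- list()
  skipped <- character(0)
  direction <- NULL
  for (nm in names(comparisons)) {
    pair <- comparisons[[nm]]
    n_pos <- sum(cls == pair[1L])
    n_neg <- sum(cls == pair[2L])
    if (n_pos < 2L || n_neg < 2L) {
      skipped <- c(skipped, nm)
      next
    }
    keep <- cls %in% pair
    fit <- fit_moderated_t(values[keep, , drop = FALSE],
                           factor(cls[keep], levels = pair))
    auc <- apply(values, 2L, function(v) {
      auroc(v[cls == pair[1L]], v[cls == pair[2L]])
    })
    tabs[[nm]] <- data.frame(antigen = colnames(values), comparison = nm,
                             p = unname(fit$p),
                             auroc = pmax(unname(auc), 1 - unname(auc)),
                             auroc_raw = unname(auc),
                             mean_diff = unname(fit$mean_diff),
                             row.names = NULL, stringsAsFactors = FALSE)
    if (nm == "active_vs_healthy") {
      direction <- stats::setNames(
        ifelse(fit$mean_diff > 0, "up", ifelse(fit$mean_diff < 0, "down", "flat")),
        colnames(values))
    }
  }
  if (length(skipped) > 0L) {
    message("skipped comparison(s) lacking a class with >= 2 samples: ",
            paste(skipped, collapse = ", "))
  }
  if (length(tabs) == 0L) stop("no comparison could be run")
  table <- do.call(rbind, tabs)
  rownames(table) <- NULL
  res <- structure(list(table = table, direction = direction,
                        skipped = skipped, p_max = p_max,
                        auroc_min = auroc_min, qualified = character(0)),
                   class = "biomarker_result")
  res$qualified <- qualify_singletons(res, p_max, auroc_min)
  res
}

#' Singleton-biomarker qualification
#'
#' An antigen qualifies if some single comparison gives both `p < p_max` and
#' `AUROC > auroc_min` (both inequalities strict, evaluated within the same
#' comparison).
#'
#' @param result a `biomarker_result`
#' @param p_max,auroc_min thresholds
#' @return character vector of qualified antigen ids (in matrix column order)
#' @export
qualify_singletons <- function(result, p_max = 0.05, auroc_min = 0.7) {
  tab <- result$table
  hit <- !is.na(tab$p) & tab$p < p_max & tab$auroc > auroc_min
  unique(tab$antigen)[unique(tab$antigen) %in% tab$antigen[hit]]
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat("Biomarker screen:", length(unique(x$table$antigen)), "antigens x",
      length(unique(x$table$comparison)), "comparisons\n")
  cat("  qualified singletons (p <", x$p_max, "and AUROC >", x$auroc_min,
      "in one comparison):", length(x$qualified), "\n")
  if (length(x$skipped) > 0L) {
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pearson redundancy matrix of biomarkers and lab values
#'
#' Pairwise Pearson correlations among antigen expression profiles and
#' (optionally) conventional lab values, using pairwise-complete samples for
#' the lab columns. Constant columns yield `NA` correlations and a warning
#' rather than a silent zero.
#'
#' @param em an `expr_matrix` or samples x antigens matrix
#' @param antigens antigen ids to include (default: all columns)
#' @param labs optional data frame of per-sample lab values aligned with and
#'   row-named by `sample_id` (e.g. columns `dsdna_positive`, `c3`, `c4`)
#' @return symmetric correlation matrix with unit diagonal
#' @export
correlation_matrix <- function(em, antigens = NULL, labs = NULL) {
  values <- if (inherits(em, "expr_matrix")) em$values else em
  if (!is.null(antigens)) values <- values[, antigens, drop = FALSE]
  if (!is.null(labs)) {
    labs <- as.matrix(labs[match(rownames(values), rownames(labs)), ,
                           drop = FALSE])
    values <- cbind(values, labs)
  }
  constant <- apply(values, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) > 0L && stats::sd(v) == 0
  })
  if (any(constant)) {
    warning("constant column(s), correlation undefined: ",
            paste(colnames(values)[constant], collapse = ", "))
  }
  suppressWarnings(stats::cor(values, use = "pairwise.complete.obs"))
}

#' Hierarchical clustering of samples and antigens
#'
#' Samples are clustered on Euclidean distance, antigens on correlation
#' distance (1 - Pearson r), both with average linkage; defaults are
#' recorded in the result. Leaf orders are returned for heat-map rendering.
#'
#' @param em an `expr_matrix` or samples x antigens matrix
#' @param sample_method,antigen_method linkage methods passed to
#'   [stats::hclust()]
#' @return list with `sample_hclust`, `antigen_hclust`, `sample_order`,
#'   `antigen_order`, `settings`
#' @export
hierarchical_cluster <- function(em, sample_method = "average",
                                 antigen_method = "average") {
  values <- if (inherits(em, "expr_matrix")) em$values else em
  if (nrow(values) < 2L) stop("clustering needs at least 2 samples")
  sh <- stats::hclust(stats::dist(values), method = sample_method)
  if (ncol(values) >= 2L) {
    cmat <- suppressWarnings(stats::cor(values))
    cmat[!is.finite(cmat)] <- 0
    ah <- stats::hclust(stats::as.dist(1 - cmat), method = antigen_method)
    antigen_order <- colnames(values)[ah$order]
  } else {
    ah <- NULL
    antigen_order <- colnames(values)
  }
  list(sample_hclust = sh, antigen_hclust = ah,
       sample_order = rownames(values)[sh$order],
       antigen_order = antigen_order,
       settings = list(sample_distance = "euclidean",
                       antigen_distance = "1 - pearson",
                       sample_method = sample_method,
                       antigen_method = antigen_method))
}

#' Export a biomarker table in six-comparison layout
#'
#' One row per antigen with p and AUROC columns per comparison (the layout
#' used to report singleton biomarkers), written as TSV.
#'
#' @param result a `biomarker_result`
#' @param panel optional `antibody_panel` used to add lineage categories
#' @param path output path, or `NULL` to just return the wide table
#' @return the wide data frame, invisibly when written
#' @export
write_biomarker_table <- function(result, panel = NULL, path = NULL) {
  tab <- result$table
  comps <- unique(tab$comparison)
  antigens <- unique(tab$antigen)
  wide <- data.frame(antigen = antigens, stringsAsFactors = FALSE)
  if (!is.null(panel)) {
    wide$category <- panel$lineage[match(antigens, panel$feature_id)]
  }
  for (cm in comps) {
    sub <- tab[tab$comparison == cm, ]
    wide[[paste0("p_", cm)]] <- sub$p[match(antigens, sub$antigen)]
    wide[[paste0("auroc_", cm)]] <- sub$auroc[match(antigens, sub$antigen)]
  }
  wide$qualified <- antigens %in% result$qualified
  if (!is.null(result$direction)) {
    wide$direction <- result$direction[antigens]
  }
  if (!is.null(path)) {
    utils::write.table(wide, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(wide))
  }
  wide
}
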
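#' Empirical ROC curve
#'
#' Stepwise ROC curve from scores and binary labels: points are ordered by
#' decreasing score threshold, tied scores are grouped (so the curve takes a
#' diagonal step across a tie block), starting at (0,0) and ending at (1,1).
#' The trapezoidal area under the returned curve equals [auroc()] exactly,
#' including under ties.
#'
#' @param scores numeric scores (higher = more positive)
#' @param labels logical (or 0/1) vector, `TRUE` = positive
#' @return data frame with columns `fpr`, `tpr`
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("roc_curve: NA input")
  np <- sum(labels)
  nn <- sum(!labels)
  if (np == 0L || nn == 0L) {
    stop("roc_curve needs both a positive and a negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  last <- !duplicated(s, fromLast = TRUE)  # one point per distinct threshold
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  data.frame(fpr = c(0, fp / nn), tpr = c(0, tp / np))
}

#' Trapezoidal area under a curve
#' @param fpr,tpr coordinates in increasing `fpr` order
#' @return area
#' @export
auc_trapezoid <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
}

# Stratified k-way partition: within each class, fold sizes differ by at
# most one; which folds receive the remainder is randomized. Returns an
# integer fold id per sample.
make_folds <- function(class, k, stratified = TRUE) {
  n <- length(class)
  folds <- integer(n)
  if (!stratified) {
    folds <- rep(seq_len(k), length.out = n)[sample.int(n)]
    return(folds)
  }
  for (cl in unique(class)) {
    idx <- which(class == cl)
    if (length(idx) < k) {
      stop("stratification failure: class '", cl, "' has ", length(idx),
           " samples, fewer than k = ", k)
    }
    lab <- rep(sample.int(k), length.out = length(idx))
    folds[idx[sample.int(length(idx))]] <- lab
  }
  folds
}

# Train on all folds but `test_fold` (using only `negative`/`positive`
# classes) and score the held-out fold; returns scores for every sample,
# NA outside the tested folds.
cv_scores <- function(values, class, folds, negative, positive,
                      rotate = TRUE, ...) {
  k <- max(folds)
  s <- rep(NA_real_, length(class))
  for (f in if (rotate) seq_len(k) else 1L) {
    train <- folds != f
    model <- sscore_model(values[train, , drop = FALSE], class[train],
                          negative = negative, positive = positive, ...)
    s[folds == f] <- predict(model, values[folds == f, , drop = FALSE])$s_score
  }
  s
}

#' Repeated random sub-sampling cross-validation of the S-score
#'
#' Repeats `B` times: draw a stratified random `k`-way partition of all
#' samples; for each fold in turn, train the S-score model on the other
#' folds (using only the two extreme training classes) and score the
#' held-out fold; pool the held-out scores of the iteration and compute the
#' AUROC of every requested comparison plus per-class mean S-scores. Reports
#' per-iteration values and their mean/SD (mean/SEM for class means) across
#' iterations.
#'
#' @param x samples x antigens matrix or `expr_matrix`
#' @param class clinical class per row
#' @param B number of iterations (default 100)
#' @param k number of folds (default 3)
#' @param seed RNG seed (required: the partitions are random)
#' @param negative,positive the extreme training classes
#' @param comparisons named list of ordered class pairs to evaluate on the
#'   held-out scores (default: the activity comparisons present in the data)
#' @param rotate if `TRUE` (default) all `k` folds serve as test set within
#'   an iteration and held-out scores are pooled; if `FALSE` only one fold
#'   is tested per iteration
#' @param stratified stratify the partition by class (default `TRUE`)
#' @param ... further arguments to [sscore_model()]
#' @return object of class `cv_result`: `auroc` (B x comparisons matrix),
#'   `class_means` (B x classes), `folds` (B x n fold ids), aggregates
#'   `auroc_mean`, `auroc_sd`, `class_mean`, `class_sem`, and `settings`
#' @export
cv_repeated_subsampling <- function(x, class, B = 100L, k = 3L, seed,
                                    negative = "healthy",
                                    positive = "sle_active",
                                    comparisons = NULL, rotate = TRUE,
                                    stratified = TRUE, ...) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  values <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (length(class) != nrow(values)) {
    stop("class must have one entry per row of x")
  }
  present <- unique(class)
  if (is.null(comparisons)) {
    comparisons <- Filter(function(p) all(p %in% present),
                          activity_comparisons())
    if (length(comparisons) == 0L) {
      comparisons <- list(extremes = c(positive, negative))
    }
  }
  for (nm in names(comparisons)) {
    miss <- setdiff(comparisons[[nm]], present)
    if (length(miss) > 0L) {
      stop("comparison '", nm, "' needs class(es) absent from the data: ",
           paste(miss, collapse = ", "))
    }
  }
  set.seed(seed)
  classes_present <- intersect(clinical_classes(), present)
  auc_mat <- matrix(NA_real_, nrow = B, ncol = length(comparisons),
                    dimnames = list(NULL, names(comparisons)))
  cm_mat <- matrix(NA_real_, nrow = B, ncol = length(classes_present),
                   dimnames = list(NULL, classes_present))
  folds_mat <- matrix(NA_integer_, nrow = B, ncol = nrow(values))
  for (b in seq_len(B)) {
    folds <- make_folds(class, k, stratified)
    folds_mat[b, ] <- folds
    s <- cv_scores(values, class, folds, negative, positive, rotate, ...)
    for (j in seq_along(comparisons)) {
      pair <- comparisons[[j]]
      sp <- s[class == pair[1L] & !is.na(s)]
      sn <- s[class == pair[2L] & !is.na(s)]
      if (length(sp) > 0L && length(sn) > 0L) {
        auc_mat[b, j] <- auroc(sp, sn)
      }
    }
    for (cl in classes_present) {
      v <- s[class == cl & !is.na(s)]
      if (length(v) > 0L) cm_mat[b, cl] <- mean(v)
    }
  }
  structure(list(
    auroc = auc_mat, class_means = cm_mat, folds = folds_mat,
    auroc_mean = colMeans(auc_mat, na.rm = TRUE),
    auroc_sd = apply(auc_mat, 2L, stats::sd, na.rm = TRUE),
    class_mean = colMeans(cm_mat, na.rm = TRUE),
    class_sem = apply(cm_mat, 2L, function(v)
      stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))),
    settings = list(B = B, k = k, seed = seed, rotate = rotate,
                    stratified = stratified, negative = negative,
                    positive = positive,
                    comparisons = comparisons)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$settings
  cat("Repeated sub-sampling CV:", s$B, "iterations of", s$k, "folds",
      if (s$stratified) "(stratified)" else "(unstratified)", "\n")
  cat("  training extremes:", s$negative, "vs", s$positive, "\n")
  for (nm in names(x$auroc_mean)) {
    cat(sprintf("  AUROC %-22s %.3f (sd %.3f)\n", nm, x$auroc_mean[nm],
                x$auroc_sd[nm]))
  }
  invisible(x)
}

#' Cross-validated pairwise two-class AUROCs
#'
#' For each class pair, independently trains and cross-validates a two-class
#' radial-kernel SVM on just those samples, and reports the mean held-out
#' AUROC with its SEM across iterations -- the all-pairs separability map of
#' the cohort (readily separable above 0.8, moderately above 0.7).
#'
#' @param x samples x antigens matrix or `expr_matrix`
#' @param class clinical class per row
#' @param class_pairs named list of ordered class pairs `c(positive,
#'   negative)`; default: every unordered pair of classes present
#' @param B,k,seed as in [cv_repeated_subsampling()]
#' @param ... further arguments to [sscore_model()]
#' @return data frame: `pair`, `positive`, `negative`, `mean_auroc`, `sem`, `B`
#' @export
pairwise_class_auroc <- function(x, class, class_pairs = NULL, B = 100L,
                                 k = 3L, seed, ...) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  values <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  present <- intersect(clinical_classes(), unique(class))
  if (is.null(class_pairs)) {
    class_pairs <- list()
    for (i in seq_along(present)) for (j in seq_len(i - 1L)) {
      nm <- paste(present[i], "vs", present[j])
      class_pairs[[nm]] <- c(present[i], present[j])
    }
  }
  rows <- lapply(seq_along(class_pairs), function(i) {
    pair <- class_pairs[[i]]
    keep <- class %in% pair
    cv <- cv_repeated_subsampling(values[keep, , drop = FALSE], class[keep],
                                  B = B, k = k, seed = seed + i,
                                  negative = pair[2L], positive = pair[1L],
                                  comparisons = stats::setNames(list(pair),
                                                                "pair"),
                                  ...)
    a <- cv$auroc[, "pair"]
    data.frame(pair = names(class_pairs)[i], positive = pair[1L],
               negative = pair[2L], mean_auroc = mean(a, na.rm = TRUE),
               sem = stats::sd(a, na.rm = TRUE) / sqrt(sum(!is.na(a))),
               B = B, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the conventional-laboratory feature matrix
#'
#' Numeric matrix of the three conventional SLE labs: anti-dsDNA positivity
#' encoded 0/1, complement C3 and C4 levels.
#'
#' @param metadata metadata data frame
#' @return samples x 3 matrix row-named by sample id
#' @export
lab_matrix <- function(metadata) {
  m <- cbind(dsdna = as.numeric(metadata$dsdna_positive),
             c3 = metadata$c3, c4 = metadata$c4)
  rownames(m) <- metadata$sample_id
  m
}

#' Compare array, laboratory and combined feature sets
#'
#' For each classification task (an ordered class pair), evaluates three
#' feature sets -- the antigen expression matrix, the conventional labs
#' (dsDNA 0/1, C3, C4) and their column-wise combination -- with repeated
#' sub-sampling cross-validation on *identical partitions* within each
#' iteration, then tests the paired per-iteration AUROC differences with
#' one-sided paired t-tests for the stated hypotheses (by default: combined
#' beats array, combined beats labs, labs beat array). The tested direction
#' is echoed in the output so a sign error cannot pass silently. With
#' `B = 1` the paired test has no degrees of freedom and is reported as
#' undefined.
#'
#' @param x samples x antigens matrix or `expr_matrix`
#' @param metadata metadata data frame (labs must be present for all samples
#'   involved in the tasks)
#' @param tasks named list of ordered class pairs `c(positive, negative)`
#' @param B,k,seed as in [cv_repeated_subsampling()]
#' @param hypotheses list of `c(better, worse)` feature-set name pairs
#' @param ... further arguments to [sscore_model()]
#' @return object of class `feature_set_comparison`: per task, the B x 3
#'   iteration AUROC matrix, feature-set means, and the paired-test table
#' @export
feature_set_comparison <- function(x, metadata,
                                   tasks = list(
                                     semi_vs_inactive = c("sle_semi",
                                                          "sle_inactive"),
                                     active_vs_inactive = c("sle_active",
                                                            "sle_inactive"),
                                     active_vs_semi = c("sle_active",
                                                        "sle_semi")),
                                   B = 100L, k = 3L, seed,
                                   hypotheses = list(c("combined", "array"),
                                                     c("combined", "labs"),
                                                     c("labs", "array")),
                                   ...) {
  if (missing(seed) || is.null(seed)) stop("seed is required")
  values <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  cls_all <- metadata$clinical_class[match(rownames(values),
                                           metadata$sample_id)]
  labs_all <- lab_matrix(metadata)[rownames(values), , drop = FALSE]
  results <- list()
  for (tname in names(tasks)) {
    pair <- tasks[[tname]]
    keep <- cls_all %in% pair
    miss <- rownames(values)[keep][!stats::complete.cases(labs_all[keep, ])]
    if (length(miss) > 0L) {
      stop("missing lab value(s) for sample(s): ",
           paste(miss, collapse = ", "))
    }
    sets <- list(array = values[keep, , drop = FALSE],
                 labs = labs_all[keep, , drop = FALSE],
                 combined = cbind(values[keep, , drop = FALSE],
                                  labs_all[keep, , drop = FALSE]))
    cls <- cls_all[keep]
    set.seed(seed)
    auc <- matrix(NA_real_, nrow = B, ncol = 3L,
                  dimnames = list(NULL, names(sets)))
    for (b in seq_len(B)) {
      folds <- make_folds(cls, k, stratified = TRUE)
      for (fs in names(sets)) {
        s <- cv_scores(sets[[fs]], cls, folds, negative = pair[2L],
                       positive = pair[1L], rotate = TRUE, ...)
        auc[b, fs] <- auroc(s[cls == pair[1L]], s[cls == pair[2L]])
      }
    }
    test_rows <- lapply(hypotheses, function(h) {
      if (B < 2L) {
        return(data.frame(hypothesis = paste(h[1L], ">", h[2L]),
                          t = NA_real_, p = NA_real_,
                          note = "undefined: B < 2 gives 0 df",
                          stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(auc[, h[1L]], auc[, h[2L]], paired = TRUE,
                          alternative = "greater")
      data.frame(hypothesis = paste(h[1L], ">", h[2L]),
                 t = unname(tt$statistic), p = tt$p.value, note = "",
                 stringsAsFactors = FALSE)
    })
    results[[tname]] <- list(task = pair, auroc = auc,
                             means = colMeans(auc),
                             tests = do.call(rbind, test_rows))
  }
  structure(list(tasks = results,
                 settings = list(B = B, k = k, seed = seed)),
            class = "feature_set_comparison")
}

#' @export
print.feature_set_comparison <- function(x, ...) {
  cat("Feature-set comparison (", x$settings$B, "shared-partition CV iterations )\n")
  for (nm in names(x$tasks)) {
    t <- x$tasks[[nm]]
    cat(sprintf("  %s: array %.3f | labs %.3f | combined %.3f\n", nm,
                t$means[["array"]], t$means[["labs"]],
                t$means[["combined"]]))
    for (i in seq_len(nrow(t$tests))) {
      cat(sprintf("    %-18s one-sided paired p = %s %s\n",
                  t$tests$hypothesis[i],
                  format.pval(t$tests$p[i], digits = 3),
                  t$tests$note[i]))
    }
  }
  invisible(x)
}
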
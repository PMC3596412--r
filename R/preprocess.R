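#' Preprocessing parameters
#'
#' @param scale_max upper end of the normalized expression scale (default 10)
#' @param low_expr_threshold low-expression cutoff: an antigen fails when the
#'   median expression among its 20% most highly expressed samples is
#'   strictly below this value (default 1, the approximate lower limit at
#'   which the technology reliably detects antigen binding)
#' @param top_fraction fraction of samples considered "most highly
#'   expressed" (default 0.2)
#' @param snr_threshold signal-to-noise cutoff: an antigen fails when the SD
#'   of its expression across samples divided by the mean absolute
#'   intra-slide replicate difference is strictly below this value
#'   (default 1.2, a conservative threshold that removes most negative
#'   control spots)
#' @return object of class `preprocess_params`
#' @export
preprocess_params <- function(scale_max = 10, low_expr_threshold = 1,
                              top_fraction = 0.2, snr_threshold = 1.2) {
  if (scale_max <= 0) stop("scale_max must be > 0")
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("top_fraction must be in (0, 1]")
  }
  if (low_expr_threshold < 0 || snr_threshold < 0) {
    stop("thresholds must be >= 0")
  }
  structure(list(scale_max = scale_max,
                 low_expr_threshold = low_expr_threshold,
                 top_fraction = top_fraction,
                 snr_threshold = snr_threshold),
            class = "preprocess_params")
}

#' Scale-normalize one slide to the 0-10 range
#'
#' Divides every replicate intensity by the slide's maximum capture-spot
#' intensity and multiplies by `scale_max`, so the brightest capture spot
#' maps to exactly `scale_max` and zero stays zero. Isotype-control and
#' anchor spots are scaled by the same factor but never contribute to the
#' maximum. The map is invariant to rescaling a slide's raw intensities by
#' any positive constant, which removes per-slide brightness differences.
#'
#' @param slide a `slide_raw`
#' @param panel the slide's `antibody_panel`
#' @param params `preprocess_params`
#' @return a `slide_raw`-shaped object with normalized intensities
#' @export
normalize_slide <- function(slide, panel, params = preprocess_params()) {
  cap <- capture_features(panel)
  mx <- max(slide$intensities[cap, ])
  if (mx <= 0) {
    stop("degenerate slide '", slide$sample_id,
         "': all capture intensities are zero")
  }
  out <- slide
  out$intensities <- slide$intensities * (params$scale_max / mx)
  out
}

#' Merge the duplicate spots of a normalized slide
#'
#' @param slide a (normalized) `slide_raw`
#' @return data frame with `feature_id`, `mean` (average of the two
#'   replicates) and `repdiff` (absolute replicate difference)
#' @export
merge_replicates <- function(slide) {
  m <- slide$intensities
  data.frame(feature_id = rownames(m),
             mean = (m[, 1L] + m[, 2L]) / 2,
             repdiff = abs(m[, 1L] - m[, 2L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble an expression matrix from raw slides
#'
#' Normalizes each slide, merges duplicates, and stacks the results into a
#' samples x features matrix with a parallel absolute-replicate-difference
#' matrix (the side-channel used by the signal-to-noise filter).
#'
#' @param slides list of `slide_raw` sharing one panel
#' @param panel the shared `antibody_panel`
#' @param params `preprocess_params`
#' @return object of class `expr_matrix`: list with `values` and `repdiff`
#'   (samples x features matrices in `[0, scale_max]`), `panel`, `params`
#' @export
build_expression_matrix <- function(slides, panel,
                                    params = preprocess_params()) {
  sample_ids <- vapply(slides, `[[`, "", "sample_id")
  if (anyDuplicated(sample_ids)) stop("duplicated sample ids across slides")
  values <- matrix(NA_real_, nrow = length(slides), ncol = nrow(panel),
                   dimnames = list(sample_ids, panel$feature_id))
  repdiff <- values
  for (i in seq_along(slides)) {
    merged <- merge_replicates(normalize_slide(slides[[i]], panel, params))
    values[i, merged$feature_id] <- merged$mean
    repdiff[i, merged$feature_id] <- merged$repdiff
  }
  structure(list(values = values, repdiff = repdiff, panel = panel,
                 params = params),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$values), "samples x", ncol(x$values),
      "features, values in [0,", x$params$scale_max, "]\n")
  invisible(x)
}

top_fraction_median <- function(x, top_fraction) {
  k <- ceiling(top_fraction * length(x))
  # stable decreasing sort: ties broken by sample order
  ord <- order(x, decreasing = TRUE, method = "radix")
  stats::median(x[ord[seq_len(k)]])
}

#' Low-expression filter
#'
#' For each antigen, takes the `ceil(top_fraction * N)` samples with the
#' highest expression of that antigen and computes the median of those
#' values; the antigen fails when that median is strictly below
#' `low_expr_threshold`.
#'
#' @param em an `expr_matrix`
#' @param params `preprocess_params`
#' @param features feature ids to evaluate (default: all capture antigens)
#' @return data frame with `feature_id`, `top20_median`, `passed_low_expression`
#' @export
low_expression_filter <- function(em, params = em$params,
                                  features = capture_features(em$panel)) {
  n <- nrow(em$values)
  if (n < 5L) {
    warning("low-expression filter with N = ", n,
            " samples: the top-", params$top_fraction * 100,
            "% set is a single sample")
  }
  med <- apply(em$values[, features, drop = FALSE], 2L,
               top_fraction_median, top_fraction = params$top_fraction)
  data.frame(feature_id = features, top20_median = unname(med),
             passed_low_expression = unname(med >= params$low_expr_threshold),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Signal-to-noise filter
#'
#' The SNR of an antigen is the standard deviation of its merged expression
#' across samples divided by the mean absolute difference between the two
#' intra-slide replicates across samples. Antigens with SNR strictly below
#' `snr_threshold` fail. A zero denominator with a non-zero numerator gives
#' infinite SNR (pass); 0/0 is degenerate (fail).
#'
#' @inheritParams low_expression_filter
#' @return data frame with `feature_id`, `snr`, `passed_snr`, `snr_reason`
#' @export
snr_filter <- function(em, params = em$params,
                       features = capture_features(em$panel)) {
  if (nrow(em$values) < 3L) {
    stop("SNR filter needs at least 3 samples")
  }
  if (is.null(em$repdiff)) {
    stop("SNR filter needs the replicate-difference side-channel")
  }
  num <- apply(em$values[, features, drop = FALSE], 2L, stats::sd)
  den <- colMeans(em$repdiff[, features, drop = FALSE])
  snr <- ifelse(den == 0, ifelse(num > 0, Inf, NaN), num / den)
  passed <- !is.nan(snr) & snr >= params$snr_threshold
  reason <- ifelse(is.nan(snr), "degenerate",
                   ifelse(passed, "", "snr below threshold"))
  data.frame(feature_id = features, snr = unname(snr),
             passed_snr = unname(passed), snr_reason = unname(reason),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Normalize, merge and quality-filter a set of slides
#'
#' Runs the full preprocessing pipeline: per-slide 0-10 scale normalization,
#' duplicate-spot merging, the low-expression filter and the
#' signal-to-noise filter. Isotype-control and anchor spots bypass the
#' filters (they are expected to fail them) but appear in the report for QC.
#'
#' @param slides list of `slide_raw` sharing one panel
#' @param panel the shared `antibody_panel`
#' @param params `preprocess_params`
#' @return list with `matrix` (an `expr_matrix` restricted to retained
#'   capture antigens) and `report` (a `filter_report` data frame with one
#'   row per panel feature: mean expression, top-20% median, SNR, pass flags,
#'   retained flag and drop reason)
#' @export
apply_filters <- function(slides, panel, params = preprocess_params()) {
  em <- build_expression_matrix(slides, panel, params)
  cap <- capture_features(panel)
  low <- low_expression_filter(em, params, cap)
  snr <- snr_filter(em, params, cap)
  report <- data.frame(
    feature_id = panel$feature_id,
    category = panel$category,
    mean_expr = colMeans(em$values)[panel$feature_id],
    top20_median = NA_real_, snr = NA_real_,
    passed_low_expression = NA, passed_snr = NA,
    retained = FALSE, reason = "control spot (bypasses filters)",
    row.names = NULL, stringsAsFactors = FALSE
  )
  i <- match(cap, report$feature_id)
  report$top20_median[i] <- low$top20_median
  report$passed_low_expression[i] <- low$passed_low_expression
  report$snr[i] <- snr$snr
  report$passed_snr[i] <- snr$passed_snr
  report$retained[i] <- low$passed_low_expression & snr$passed_snr
  report$reason[i] <- ifelse(
    report$retained[i], "",
    ifelse(!low$passed_low_expression, "low expression",
           ifelse(snr$snr_reason == "degenerate", "degenerate",
                  "low snr")))
  # QC: compute the control-spot statistics too, without letting them vote
  ctrl <- setdiff(panel$feature_id, cap)
  if (length(ctrl) > 0L) {
    j <- match(ctrl, report$feature_id)
    report$top20_median[j] <-
      low_expression_filter(em, params, ctrl)$top20_median
    report$snr[j] <- snr_filter(em, params, ctrl)$snr
  }
  class(report) <- c("filter_report", "data.frame")
  retained <- report$feature_id[report$retained]
  em$values <- em$values[, retained, drop = FALSE]
  em$repdiff <- em$repdiff[, retained, drop = FALSE]
  list(matrix = em, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cap <- x$category == "capture"
  cat("Filter report:", sum(cap), "capture antigens;",
      sum(x$retained[cap]), "retained,",
      sum(cap & !x$retained & x$reason == "low expression"),
      "failed low-expression,",
      sum(cap & !x$retained & x$reason != "low expression"),
      "failed SNR/degenerate\n")
  invisible(x)
}

#' Write a filter report as TSV and JSON
#'
#' @param report a `filter_report`
#' @param path_tsv,path_json output paths (either may be `NULL` to skip)
#' @return invisibly, the report
#' @export
write_filter_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(report, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(report, path_json, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(report)
}

#' Write an expression matrix with a provenance header
#'
#' Long format: `sample_id<TAB>feature_id<TAB>value<TAB>repdiff`, preceded by
#' `#params` header lines recording the preprocessing parameters.
#'
#' @param em an `expr_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression_matrix <- function(em, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- em$params
  writeLines(sprintf(
    "#params scale_max=%s low_expr_threshold=%s top_fraction=%s snr_threshold=%s",
    p$scale_max, p$low_expr_threshold, p$top_fraction, p$snr_threshold), con)
  long <- data.frame(
    sample_id = rep(rownames(em$values), times = ncol(em$values)),
    feature_id = rep(colnames(em$values), each = nrow(em$values)),
    value = as.vector(em$values),
    repdiff = as.vector(em$repdiff))
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
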
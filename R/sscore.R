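#' Fit a disease-activity S-score model
#'
#' Trains a radial-basis-kernel support-vector classifier on the two extreme
#' classes only (by default healthy controls versus active SLE) and turns its
#' signed decision value \eqn{f(x)} -- the distance-proxy from the decision
#' boundary -- into an activity score. Because disease activity is assumed to
#' follow a linear trend, profiles of intermediate classes, never seen in
#' training, are expected to land between the extremes. The orientation sign
#' is calibrated on the training data so that higher S-scores mean more
#' active disease.
#'
#' @param x samples x antigens numeric matrix (rownames = sample ids), or an
#'   `expr_matrix`
#' @param class character vector of clinical classes, one per row of `x`
#' @param negative,positive the two training classes (low / high activity)
#' @param cost SVM cost parameter (default 1, the standard default)
#' @param gamma radial-kernel width; default `1 / ncol(x)`, the standard
#'   default
#' @param standardize centre and scale features using statistics computed on
#'   the training rows only (default `TRUE`)
#' @param transform `"identity"` (S-score = oriented decision value) or
#'   `"logistic"` (squashes to (0,1); a boundary profile scores 0.5); both
#'   are monotone in \eqn{f(x)}
#' @return object of class `sscore_model`
#' @seealso [predict.sscore_model()], [score_cohort()]
#' @export
sscore_model <- function(x, class, negative = "healthy",
                         positive = "sle_active", cost = 1, gamma = NULL,
                         standardize = TRUE,
                         transform = c("identity", "logistic")) {
  transform <- match.arg(transform)
  values <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (length(class) != nrow(values)) {
    stop("class must have one entry per row of x")
  }
  if (ncol(values) < 1L) stop("feature list is empty")
  n_neg <- sum(class == negative)
  n_pos <- sum(class == positive)
  if (n_neg < 2L || n_pos < 2L) {
    stop("training failure: need >= 2 samples of each extreme class ('",
         negative, "': ", n_neg, ", '", positive, "': ", n_pos, ")")
  }
  keep <- class %in% c(negative, positive)
  xt <- values[keep, , drop = FALSE]
  yt <- factor(class[keep], levels = c(negative, positive))
  if (standardize) {
    center <- colMeans(xt)
    scale_ <- apply(xt, 2L, stats::sd)
    scale_[scale_ == 0] <- 1
  } else {
    center <- rep(0, ncol(xt))
    scale_ <- rep(1, ncol(xt))
  }
  names(center) <- names(scale_) <- colnames(xt)
  xs <- sweep(sweep(xt, 2L, center), 2L, scale_, `/`)
  if (is.null(gamma)) gamma <- 1 / ncol(xs)
  fit <- e1071::svm(xs, yt, kernel = "radial", cost = cost, gamma = gamma,
                    scale = FALSE)
  dv <- attr(stats::predict(fit, xs, decision.values = TRUE),
             "decision.values")[, 1L]
  orientation <- if (mean(dv[yt == positive]) >= mean(dv[yt == negative]))
    1 else -1
  structure(list(fit = fit, features = colnames(xs), center = center,
                 scale = scale_, orientation = orientation,
                 transform = transform, cost = cost, gamma = gamma,
                 standardize = standardize,
                 classes = c(negative = negative, positive = positive),
                 training_samples = rownames(xt),
                 call = match.call()),
            class = "sscore_model")
}

apply_transform <- function(f, transform) {
  switch(transform, identity = f, logistic = 1 / (1 + exp(-f)))
}

#' Score expression profiles with a fitted S-score model
#'
#' @param object an `sscore_model`
#' @param newdata samples x antigens matrix (or `expr_matrix`) containing at
#'   least the model's features
#' @param ... unused
#' @return data frame with `sample_id`, `f_value` (oriented decision value)
#'   and `s_score` (after the model's transform); higher = more active
#' @export
predict.sscore_model <- function(object, newdata, ...) {
  values <- if (inherits(newdata, "expr_matrix")) newdata$values
            else as.matrix(newdata)
  missing <- setdiff(object$features, colnames(values))
  if (length(missing) > 0L) {
    stop("scoring failure: profile missing antigen(s): ",
         paste(missing, collapse = ", "))
  }
  values <- values[, object$features, drop = FALSE]
  xs <- sweep(sweep(values, 2L, object$center), 2L, object$scale, `/`)
  dv <- attr(stats::predict(object$fit, xs, decision.values = TRUE),
             "decision.values")[, 1L]
  f <- object$orientation * dv
  data.frame(sample_id = if (is.null(rownames(values)))
               seq_len(nrow(values)) else rownames(values),
             f_value = unname(f),
             s_score = unname(apply_transform(f, object$transform)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.sscore_model <- function(x, ...) {
  cat("S-score model (radial-kernel SVM, cost =", x$cost,
      ", gamma =", format(x$gamma, digits = 4), ")\n")
  cat("  trained on extremes:", x$classes[["negative"]], "vs",
      x$classes[["positive"]], "(", length(x$training_samples),
      "samples,", length(x$features), "antigens )\n")
  cat("  transform:", x$transform, "; orientation:",
      ifelse(x$orientation > 0, "+1", "-1"),
      "(higher score = more active)\n")
  invisible(x)
}

#' @export
summary.sscore_model <- function(object, ...) {
  print(object)
  dv <- object$orientation * object$fit$decision.values[, 1L]
  y <- object$fit$fitted
  pos <- object$classes[["positive"]]
  cat("  training decision values:",
      object$classes[["negative"]], "mean",
      format(mean(dv[y != pos]), digits = 4), ";",
      pos, "mean", format(mean(dv[y == pos]), digits = 4), "\n")
  cat("  support vectors:", object$fit$tot.nSV, "\n")
  invisible(object)
}

#' Per-class mean S-scores with standard errors
#'
#' Scores a cohort and summarises the S-score per clinical class: mean,
#' standard error of the mean (`NA` for single-sample classes), and n.
#'
#' @param model an `sscore_model`
#' @param x samples x antigens matrix or `expr_matrix`
#' @param class character vector of clinical classes, one per row
#' @return data frame with `class`, `n`, `mean_s`, `sem`
#' @export
score_cohort <- function(model, x, class) {
  values <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (nrow(values) == 0L) stop("empty cohort")
  if (length(class) != nrow(values)) {
    stop("class must have one entry per row of x")
  }
  sc <- predict(model, values)
  agg <- lapply(split(sc$s_score, class), function(v) {
    c(n = length(v), mean_s = mean(v),
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- data.frame(class = names(agg), do.call(rbind, agg),
                    row.names = NULL, stringsAsFactors = FALSE)
  lev <- intersect(clinical_classes(), out$class)
  out[order(match(out$class, c(lev, setdiff(out$class, lev)))), , drop = FALSE]
}

#' Plot per-class mean S-scores
#'
#' Bar plot of class-mean S-scores with SEM error bars, ordered by activity
#' grade.
#'
#' @param x an `sscore_model`
#' @param data samples x antigens matrix or `expr_matrix`
#' @param class character vector of clinical classes
#' @param ... passed to [graphics::barplot()]
#' @export
plot.sscore_model <- function(x, data, class, ...) {
  cm <- score_cohort(x, data, class)
  bp <- graphics::barplot(cm$mean_s, names.arg = cm$class,
                          ylab = "mean S-score",
                          ylim = range(0, cm$mean_s + 2 * cm$sem,
                                       cm$mean_s - 2 * cm$sem, na.rm = TRUE),
                          ...)
  ok <- !is.na(cm$sem)
  graphics::arrows(bp[ok], cm$mean_s[ok] - cm$sem[ok],
                   bp[ok], cm$mean_s[ok] + cm$sem[ok],
                   angle = 90, code = 3, length = 0.05)
  invisible(cm)
}

#' Serialize an S-score model description to JSON
#'
#' Writes a self-describing text archive of the model: feature list, kernel
#' parameters, standardization statistics, orientation, transform and
#' training-set provenance. (The kernel expansion itself is refit from data;
#' the archive documents the model, it is not a binary snapshot.)
#'
#' @param model an `sscore_model`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sscore_model <- function(model, path) {
  desc <- list(model = "sscore",
               kernel = "radial", cost = model$cost, gamma = model$gamma,
               standardize = model$standardize,
               transform = model$transform,
               orientation = model$orientation,
               classes = as.list(model$classes),
               features = model$features,
               center = as.list(model$center),
               scale = as.list(model$scale),
               training_samples = model$training_samples,
               n_support_vectors = model$fit$tot.nSV)
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
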
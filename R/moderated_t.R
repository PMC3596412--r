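# Inverse of the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear; converges in a handful of steps for any y > 0.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Empirical-Bayes fit of a scaled inverse chi-square prior to observed
# per-antigen sample variances s2 with d residual df each, by moment
# matching on log s2 (method-of-moments on the log-F distribution):
# returns prior df d0 and prior variance s02. Antigens with s2 == 0 are
# excluded from hyperparameter estimation but still receive shrinkage.
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stop("need at least 2 antigens with positive variance")
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  G <- length(e)
  evar <- sum((e - emean)^2) / (G - 1L) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(d0 = d0, s02 = s02)
}

#' Moderated two-sample t-test across antigens
#'
#' Computes, for every antigen, the two-sample t-statistic with an
#' empirical-Bayes moderated variance: per-antigen pooled variances
#' \eqn{s_g^2} (residual df \eqn{d_g = n_1 + n_2 - 2}) are shrunk toward a
#' prior variance \eqn{s_0^2} with prior df \eqn{d_0} estimated by moment
#' matching on \eqn{\log s_g^2},
#' \deqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g),}
#' and the moderated statistic
#' \eqn{\tilde{t}_g = (\bar{x}_{g1} - \bar{x}_{g2}) /
#' (\tilde{s}_g \sqrt{1/n_1 + 1/n_2})} is referred to a t distribution with
#' \eqn{d_0 + d_g} degrees of freedom (normal when \eqn{d_0 = \infty}).
#' Pooling variance information across antigens stabilises the denominator
#' when per-group sample sizes are small, the regime of these arrays.
#'
#' @param values samples x antigens numeric matrix (or an `expr_matrix`)
#' @param group factor or character vector, one entry per sample, with
#'   exactly two levels; the first level of the factor is the "positive"
#'   group (its mean enters with positive sign)
#' @param prior_df optional override of the estimated prior df \eqn{d_0};
#'   `prior_df = 0` reproduces the classical pooled two-sample t-test
#' @return object of class `moderated_t_fit`: data frame-like list with
#'   per-antigen `mean_diff`, `s2`, `t`, `df_total`, `p`, and hyperparameters
#'   `d0`, `s02`, `d` (residual df)
#' @export
fit_moderated_t <- function(values, group, prior_df = NULL) {
  if (inherits(values, "expr_matrix")) values <- values$values
  group <- factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  n1 <- sum(group == levels(group)[1L])
  n2 <- sum(group == levels(group)[2L])
  if (min(n1, n2) < 2L) {
    stop("insufficient data: each group needs at least 2 samples (got ",
         n1, " and ", n2, ")")
  }
  if (ncol(values) < 2L) {
    stop("hyperparameter estimation pools across antigens; need >= 2")
  }
  x1 <- values[group == levels(group)[1L], , drop = FALSE]
  x2 <- values[group == levels(group)[2L], , drop = FALSE]
  m1 <- colMeans(x1)
  m2 <- colMeans(x2)
  ss1 <- colSums(sweep(x1, 2L, m1)^2)
  ss2 <- colSums(sweep(x2, 2L, m2)^2)
  d <- n1 + n2 - 2L
  s2 <- (ss1 + ss2) / d
  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, d)
  } else {
    if (prior_df < 0) stop("prior_df must be >= 0")
    prior <- list(d0 = prior_df,
                  s02 = if (prior_df > 0) fit_variance_prior(s2, d)$s02 else NA_real_)
  }
  d0 <- prior$d0
  s02 <- prior$s02
  if (is.infinite(d0)) {
    stilde2 <- rep(s02, length(s2))
  } else if (d0 == 0) {
    stilde2 <- s2
  } else {
    stilde2 <- (d0 * s02 + d * s2) / (d0 + d)
  }
  se <- sqrt(stilde2 * (1 / n1 + 1 / n2))
  tval <- (m1 - m2) / se
  tval[se == 0] <- NaN
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tval), df = df_total)
  p[is.nan(tval)] <- NA_real_
  structure(list(antigen = colnames(values), mean1 = m1, mean2 = m2,
                 mean_diff = m1 - m2, s2 = s2, stilde2 = stilde2,
                 t = tval, df_total = rep(df_total, length(tval)), p = p,
                 d0 = d0, s02 = s02, d = d, n1 = n1, n2 = n2,
                 groups = levels(group)),
            class = "moderated_t_fit")
}

#' @export
print.moderated_t_fit <- function(x, ...) {
  cat("Moderated t fit:", length(x$antigen), "antigens;",
      x$groups[1L], "(n =", x$n1, ") vs", x$groups[2L], "(n =", x$n2, ")\n")
  cat("  prior df d0 =", format(x$d0, digits = 4),
      "; prior variance s0^2 =", format(x$s02, digits = 4), "\n")
  cat("  antigens with p < 0.05:", sum(x$p < 0.05, na.rm = TRUE), "\n")
  invisible(x)
}

#' @export
as.data.frame.moderated_t_fit <- function(x, ...) {
  data.frame(antigen = x$antigen, mean_diff = x$mean_diff, s2 = x$s2,
             stilde2 = x$stilde2, t = x$t, df_total = x$df_total, p = x$p,
             row.names = NULL, stringsAsFactors = FALSE)
}
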
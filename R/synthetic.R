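#' Default per-class lab-abnormality model
#'
#' Per-class probabilities of anti-dsDNA positivity and of low complement C3
#' and C4. The SLE rows reproduce the rates observed in the motivating
#' cohort (dsDNA-positive 91% of active, 56% of semi-active, 24% of inactive
#' patients; low C3 64/63/24%; low C4 64/44/21%). Healthy and disease-control
#' rates are set to small background values.
#'
#' @return data frame with columns `class`, `p_dsdna`, `p_c3_low`, `p_c4_low`
#' @export
default_lab_model <- function() {
  data.frame(
    class = clinical_classes(),
    p_dsdna  = c(0.02, 0.24, 0.56, 0.91, 0.05, 0.10),
    p_c3_low = c(0.02, 0.24, 0.63, 0.64, 0.05, 0.08),
    p_c4_low = c(0.02, 0.21, 0.44, 0.64, 0.05, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Default activity-graded effect profile
#'
#' Standardized (units of the biological log-scale SD) per-class expression
#' shifts for the antigens with activity-dependent expression: T- and
#' NK-cell surface markers plus CD52 and the light chains are down-regulated
#' with SLE activity, CD66c and CD95 up-regulated. Shift magnitude grows with
#' activity grade (fractions 0.4 / 0.7 / 1.1 of the per-antigen magnitude
#' for inactive / semi-active / active, calibrated so that held-out
#' class-mean S-scores reproduce the monotone activity ordering the score
#' is meant to recover). RA and other autoimmune classes get
#' attenuated shifts on a subset of the same antigens, so they partially
#' overlap the SLE signature.
#'
#' @param panel an `antibody_panel`; must contain the named antigens
#' @return numeric matrix, capture antigens x clinical classes, of signed
#'   standardized shifts (zero rows for unaffected antigens)
#' @export
default_effect_profile <- function(panel) {
  magnitudes <- c(TCRab = -0.9, CD2 = -1.6, CD3 = -1.3, CD4 = -1.1,
                  CD5 = -1.6, CD7 = -1.7, CD8 = -1.2, CD28 = -0.8,
                  CD45RA = -1.1, CD56 = -1.1, CD57 = -0.9, CD52 = -1.2,
                  kappa = -0.9, lambda = -0.7, CD66c = 1.0, CD95 = 0.8)
  cap <- capture_features(panel)
  missing <- setdiff(names(magnitudes), cap)
  if (length(missing) > 0L) {
    stop("effect_profile validation failure: antigen(s) not in panel: ",
         paste(missing, collapse = ", "))
  }
  eff <- matrix(0, nrow = length(cap), ncol = length(clinical_classes()),
                dimnames = list(cap, clinical_classes()))
  eff[names(magnitudes), "sle_inactive"] <- 0.4 * magnitudes
  eff[names(magnitudes), "sle_semi"]     <- 0.7 * magnitudes
  eff[names(magnitudes), "sle_active"]   <- 1.1 * magnitudes
  ra_overlap <- c("CD2", "CD3", "CD5", "CD7", "CD45RA", "CD52", "kappa")
  other_overlap <- c("CD3", "CD5", "CD56", "lambda", "CD52")
  eff[ra_overlap, "ra"] <- 0.5 * eff[ra_overlap, "sle_semi"]
  eff[other_overlap, "other_ai"] <- 0.35 * eff[other_overlap, "sle_semi"]
  eff
}

#' Synthetic-cohort configuration
#'
#' Bundles and validates every parameter of the synthetic-cohort generator.
#' Defaults reproduce the composition of the motivating study (24 healthy,
#' 33 inactive, 16 semi-active and 11 active SLE, 25 RA, 28 other autoimmune
#' assessments) with the default activity-graded effect profile and lab
#' model.
#'
#' @param n_per_class named integer vector of per-class sample counts
#' @param panel `antibody_panel` (default [default_panel()])
#' @param effect_profile capture-antigens x classes matrix of standardized
#'   log-scale shifts, or `NULL` for [default_effect_profile()]
#' @param baseline_log_mean,baseline_log_sd mean and SD of the per-antigen
#'   baseline log-intensities (raw intensities are log-normal)
#' @param bio_log_sd biological between-sample SD on the log scale; effect
#'   shifts are expressed in units of this SD
#' @param replicate_noise_sd SD of the additive intra-slide replicate noise,
#'   in raw densitometry units (truncated so intensities stay non-negative)
#' @param frac_low_expression fraction of unaffected capture antigens drawn
#'   near the detection floor (they fail the low-expression filter)
#' @param lineage_cor shared-factor correlation among markers of the same
#'   lineage (T / NK / B)
#' @param slide_scale_sd log-scale SD of the per-slide brightness factor
#' @param lab_model per-class lab-abnormality probabilities
#'   (default [default_lab_model()])
#' @param seed integer RNG seed; identical configs give identical cohorts
#' @return object of class `cohort_config`
#' @export
cohort_config <- function(n_per_class = c(healthy = 24, sle_inactive = 33,
                                          sle_semi = 16, sle_active = 11,
                                          ra = 25, other_ai = 28),
                          panel = default_panel(),
                          effect_profile = NULL,
                          baseline_log_mean = 6.5,
                          baseline_log_sd = 0.45,
                          bio_log_sd = 0.35,
                          replicate_noise_sd = 25,
                          frac_low_expression = 0.25,
                          lineage_cor = 0.7,
                          slide_scale_sd = 0.25,
                          lab_model = default_lab_model(),
                          seed = 1L) {
  if (is.null(effect_profile)) effect_profile <- default_effect_profile(panel)
  n_per_class <- unlist(n_per_class)  # tolerate YAML/JSON list configs
  bad <- setdiff(names(n_per_class), clinical_classes())
  if (length(bad) > 0L) {
    stop("invalid config field 'n_per_class': unknown class ",
         paste(bad, collapse = ", "))
  }
  if (any(n_per_class < 0) || any(n_per_class != round(n_per_class))) {
    stop("invalid config field 'n_per_class': counts must be integers >= 0")
  }
  if (replicate_noise_sd < 0) {
    stop("invalid config field 'replicate_noise_sd': must be >= 0")
  }
  for (fld in c("frac_low_expression", "lineage_cor")) {
    v <- get(fld)
    if (v < 0 || v > 1) {
      stop("invalid config field '", fld, "': must be in [0, 1]")
    }
  }
  probs <- unlist(lab_model[, c("p_dsdna", "p_c3_low", "p_c4_low")])
  if (any(probs < 0 | probs > 1)) {
    stop("invalid config field 'lab_model': probabilities must be in [0, 1]")
  }
  cap <- capture_features(panel)
  if (is.null(rownames(effect_profile)) ||
      length(setdiff(rownames(effect_profile), cap)) > 0L) {
    stop("invalid config field 'effect_profile': row(s) not capture antigens: ",
         paste(setdiff(rownames(effect_profile), cap), collapse = ", "))
  }
  if (length(setdiff(colnames(effect_profile), clinical_classes())) > 0L) {
    stop("invalid config field 'effect_profile': unknown class column")
  }
  full <- matrix(0, nrow = length(cap), ncol = length(clinical_classes()),
                 dimnames = list(cap, clinical_classes()))
  full[rownames(effect_profile), colnames(effect_profile)] <- effect_profile
  if (length(seed) != 1L || is.na(seed) || seed != round(seed)) {
    stop("invalid config field 'seed': must be a single integer")
  }
  structure(list(n_per_class = n_per_class, panel = panel,
                 effect_profile = full,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 bio_log_sd = bio_log_sd,
                 replicate_noise_sd = replicate_noise_sd,
                 frac_low_expression = frac_low_expression,
                 lineage_cor = lineage_cor,
                 slide_scale_sd = slide_scale_sd,
                 lab_model = lab_model, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a synthetic leukocyte-capture cohort
#'
#' Simulates duplicate-spot raw slides plus clinical metadata with the
#' statistical structure the downstream analysis assumes: log-normal
#' baseline intensities, additive class effects on the log scale (graded
#' with SLE activity), a shared latent factor per lineage (so T-, NK- and
#' B-cell markers are co-expressed), a per-slide brightness factor removed
#' by per-slide normalization, additive intra-slide replicate noise, a
#' planted set of detection-floor antigens, and per-class lab values drawn
#' independently of the array noise.
#'
#' @param config a `cohort_config`
#' @return object of class `synthetic_cohort`: list with `slides` (list of
#'   `slide_raw`), `metadata` (data frame), and `truth` (ground truth:
#'   per-antigen per-class true log means, per-sample latent activity grade,
#'   planted low-expression antigens, true lab status)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  panel <- config$panel
  cap <- capture_features(panel)
  classes <- rep(names(config$n_per_class), config$n_per_class)
  n <- length(classes)
  if (n == 0L) stop("invalid config field 'n_per_class': no samples requested")
  sample_ids <- sprintf("S%03d", seq_len(n))

  # planted detection-floor antigens, chosen among antigens with no class
  # effect so the signal antigens always survive the low-expression filter
  eff <- config$effect_profile
  unaffected <- cap[rowSums(abs(eff)) == 0]
  n_low <- round(config$frac_low_expression * length(cap))
  if (n_low > length(unaffected)) {
    stop("invalid config field 'frac_low_expression': only ",
         length(unaffected), " unaffected antigens available")
  }
  low_antigens <- sort(sample(unaffected, n_low))

  mu <- stats::rnorm(length(cap), config$baseline_log_mean,
                     config$baseline_log_sd)
  names(mu) <- cap
  floor_log_mean <- config$baseline_log_mean - 4.5
  mu[low_antigens] <- stats::rnorm(n_low, floor_log_mean, 0.3)
  # isotype controls sit near the detection floor; the CD44 anchor is bright
  mu_ctrl <- stats::setNames(rep(floor_log_mean, sum(panel$category != "capture")),
                             panel$feature_id[panel$category != "capture"])
  mu_ctrl[panel$feature_id[panel$category == "anchor"]] <-
    config$baseline_log_mean + 1.2
  mu_all <- c(mu, mu_ctrl)[panel$feature_id]

  lineage <- stats::setNames(panel$lineage, panel$feature_id)[panel$feature_id]
  loading <- ifelse(lineage %in% c("T", "NK", "B") &
                      panel$category == "capture",
                    sqrt(config$lineage_cor), 0)

  shift_all <- matrix(0, nrow = length(panel$feature_id),
                      ncol = length(clinical_classes()),
                      dimnames = list(panel$feature_id, clinical_classes()))
  shift_all[cap, ] <- eff

  g <- length(panel$feature_id)
  fac <- matrix(stats::rnorm(n * 3L), nrow = n,
                dimnames = list(NULL, c("T", "NK", "B")))
  eps <- matrix(stats::rnorm(n * g), nrow = n)
  fac_full <- matrix(0, nrow = n, ncol = g)
  for (lin in c("T", "NK", "B")) {
    idx <- which(lineage == lin)
    fac_full[, idx] <- fac[, lin]
  }
  e <- sweep(fac_full, 2L, loading, `*`) +
    sweep(eps, 2L, sqrt(1 - loading^2), `*`)
  z <- sweep(e, 2L, mu_all, function(a, b) b + config$bio_log_sd * a)
  z <- z + config$bio_log_sd * t(shift_all[, classes, drop = FALSE])
  slide_scale <- exp(stats::rnorm(n, 0, config$slide_scale_sd))
  expected <- exp(z) * slide_scale

  slides <- vector("list", n)
  for (i in seq_len(n)) {
    reps <- expected[i, ] +
      stats::rnorm(2L * g, 0, config$replicate_noise_sd)
    m <- pmax(matrix(reps, ncol = 2L), 0)
    rownames(m) <- panel$feature_id
    slides[[i]] <- slide_raw(sample_ids[i], m, panel)
  }

  lab <- config$lab_model[match(classes, config$lab_model$class), ]
  dsdna <- stats::rbinom(n, 1L, lab$p_dsdna)
  c3_low <- stats::rbinom(n, 1L, lab$p_c3_low) == 1L
  c4_low <- stats::rbinom(n, 1L, lab$p_c4_low) == 1L
  c3 <- ifelse(c3_low, stats::runif(n, 0.35, 0.85), stats::runif(n, 0.9, 1.8))
  c4 <- ifelse(c4_low, stats::runif(n, 0.05, 0.15), stats::runif(n, 0.16, 0.5))
  sledai <- rep(NA_integer_, n)
  sledai[classes == "sle_inactive"] <-
    sample(0:4, sum(classes == "sle_inactive"), replace = TRUE)
  sledai[classes == "sle_semi"] <-
    sample(5:7, sum(classes == "sle_semi"), replace = TRUE)
  sledai[classes == "sle_active"] <-
    sample(8:16, sum(classes == "sle_active"), replace = TRUE)

  metadata <- validate_metadata(data.frame(
    sample_id = sample_ids, clinical_class = classes, sledai = sledai,
    dsdna_positive = dsdna, c3 = c3, c4 = c4, stringsAsFactors = FALSE))

  class_log_means <- mu[cap] + config$bio_log_sd * eff  # recycles by column
  truth <- list(class_log_means = class_log_means,
                activity_grade = activity_grade(classes),
                low_antigens = low_antigens,
                c3_low = c3_low, c4_low = c4_low,
                baseline_log_mean = mu)
  structure(list(slides = slides, metadata = metadata, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x$slides), "slides,",
      length(capture_features(x$config$panel)), "capture antigens, seed",
      x$config$seed, "\n")
  print(table(x$metadata$clinical_class))
  invisible(x)
}

#' Generate a null cohort (no class effects)
#'
#' Identical to [generate_cohort()] but with every entry of the effect
#' profile forced to zero, so no antigen carries class information; used for
#' type-I-error and null-AUROC calibration.
#'
#' @param config a `cohort_config`
#' @return a `synthetic_cohort`
#' @export
generate_null_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  config$effect_profile[] <- 0
  generate_cohort(config)
}

#' Cohort configuration with balanced array and laboratory signal
#'
#' A two-class (SLE inactive vs semi-active) cohort configuration for
#' studying the complementary-information gain of combining the antigen
#' array with the conventional labs. The array's semi-vs-inactive
#' discrimination is made comparable in strength to the labs' (effect
#' fractions 0.2 / 0.9 instead of the default 0.4 / 0.7), and both classes
#' get `n` samples so cross-validated AUROC differences are stable. Lab
#' values remain independent of the CD-marker noise by construction, so the
#' two blocks carry independent, similarly strong signal -- the regime in
#' which a combined classifier can be expected to beat either block alone.
#' (Under the default study-sized cohort the array's semi-vs-inactive signal
#' is much weaker than the labs', and concatenating it dilutes rather than
#' helps; see the methods vignette.)
#'
#' @param seed integer RNG seed
#' @param n samples per class (default 40)
#' @return a `cohort_config`
#' @export
balanced_signal_config <- function(seed, n = 40L) {
  panel <- default_panel()
  eff <- default_effect_profile(panel)
  eff[, "sle_inactive"] <- eff[, "sle_inactive"] / 0.4 * 0.2
  eff[, "sle_semi"] <- eff[, "sle_semi"] / 0.7 * 0.9
  cohort_config(n_per_class = c(sle_inactive = n, sle_semi = n),
                panel = panel, effect_profile = eff, seed = seed)
}

#' Write a synthetic cohort to disk
#'
#' Writes `slides.tsv`, `metadata.tsv` and `panel.tsv` in the package's
#' tab-separated formats, each with `#` provenance header lines carrying the
#' generator seed.
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  prov <- c(paste0("generator=slescore ",
                   as.character(utils::packageVersion("slescore"))),
            paste0("seed=", cohort$config$seed))
  write_slides(cohort$slides, file.path(dir, "slides.tsv"),
               header_lines = prov)
  write_metadata(cohort$metadata, file.path(dir, "metadata.tsv"),
                 header_lines = prov)
  write_panel(cohort$config$panel, file.path(dir, "panel.tsv"))
  invisible(dir)
}
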
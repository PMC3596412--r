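#' Build a run configuration
#'
#' Assembles and validates the configuration of an end-to-end pipeline run.
#' A configuration may also be read from a YAML or JSON file with
#' [read_run_config()]; the file mirrors these fields.
#'
#' @param outdir output directory for all stage artifacts
#' @param seed integer seed; mandatory whenever a stochastic stage
#'   (`simulate`, `evaluate`) is enabled
#' @param stages character vector of stages to run, in pipeline order, from
#'   `c("simulate", "preprocess", "biomarkers", "score", "evaluate",
#'   "report")`; input stages may be replaced by pre-existing files via
#'   `inputs`
#' @param cohort list of [cohort_config()] arguments for the `simulate`
#'   stage (ignored when slides are read from `inputs`)
#' @param inputs optional list with paths `slides`, `metadata`, `panel` to
#'   analyse existing data instead of simulating
#' @param preprocess list of [preprocess_params()] arguments
#' @param biomarkers list with `p_max`, `auroc_min`
#' @param score list with `transform` (`"identity"` or `"logistic"`)
#' @param evaluate list with `B`, `k` and optionally `feature_sets = FALSE`
#'   to skip the array/labs/combined comparison
#' @return object of class `run_config`
#' @export
run_config <- function(outdir, seed = NULL,
                       stages = c("simulate", "preprocess", "biomarkers",
                                  "score", "evaluate", "report"),
                       cohort = list(), inputs = NULL,
                       preprocess = list(), biomarkers = list(),
                       score = list(), evaluate = list()) {
  if (!is.null(seed)) seed <- as.integer(seed)
  known <- c("simulate", "preprocess", "biomarkers", "score", "evaluate",
             "report")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- known[known %in% stages]
  if (is.null(seed) && any(c("simulate", "evaluate") %in% stages)) {
    stop("config validation failure: 'seed' is mandatory when a stochastic ",
         "stage (simulate, evaluate) is enabled")
  }
  if (!"simulate" %in% stages && any(c("preprocess", "biomarkers", "score",
                                       "evaluate") %in% stages)) {
    if (is.null(inputs) || !all(c("slides", "metadata", "panel") %in%
                                names(inputs))) {
      stop("config validation failure: without the simulate stage, 'inputs' ",
           "must provide paths 'slides', 'metadata' and 'panel'")
    }
    missing <- unlist(inputs)[!file.exists(unlist(inputs))]
    if (length(missing) > 0L) {
      stop("config validation failure: input file(s) not found: ",
           paste(missing, collapse = ", "))
    }
  }
  structure(list(outdir = outdir, seed = seed, stages = stages,
                 cohort = cohort, inputs = inputs, preprocess = preprocess,
                 biomarkers = biomarkers, score = score, evaluate = evaluate),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json` whose fields mirror
#'   the arguments of [run_config()]
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be a .yaml/.yml or .json file"))
  args <- raw[intersect(names(raw), names(formals(run_config)))]
  do.call(run_config, args)
}

# Canonical JSON serialization of a config (panel and matrices included by
# value), hashed for the provenance manifest. The output directory is not
# part of the analysis identity and is excluded.
config_hash <- function(config) {
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  plain$outdir <- NULL
  json <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in order (simulate or ingest inputs,
#' preprocess, biomarker screen, S-score, cross-validated evaluation,
#' report), writing every stage's artifacts into `config$outdir` and a
#' provenance manifest (`manifest.json`) recording the package version,
#' config hash, seed and per-file checksums. A failing stage halts the run,
#' leaves earlier artifacts in place and writes a `FAILED` marker naming the
#' stage. Reruns with an identical config and seed produce identical
#' artifacts.
#'
#' @param config a `run_config`, or a path to a YAML/JSON config file
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  unlink(file.path(outdir, "FAILED"))
  state <- list(config = config)
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      writeLines(paste0("stage=", name, "\nerror=", conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  run_stage("simulate", function() {
    cc <- do.call(cohort_config,
                  c(config$cohort, list(seed = config$seed)))
    cohort <- generate_cohort(cc)
    write_cohort(cohort, outdir)
    state$cohort <<- cohort
  })
  if (!"simulate" %in% config$stages && !is.null(config$inputs)) {
    panel <- read_panel(config$inputs$panel)
    state$cohort <- list(
      slides = read_slides(config$inputs$slides, panel),
      metadata = read_metadata(config$inputs$metadata),
      config = list(panel = panel))
  }

  run_stage("preprocess", function() {
    params <- do.call(preprocess_params, config$preprocess)
    filt <- apply_filters(state$cohort$slides, state$cohort$config$panel,
                          params)
    write_expression_matrix(filt$matrix,
                            file.path(outdir, "expression_matrix.tsv"))
    write_filter_report(filt$report,
                        file.path(outdir, "filter_report.tsv"),
                        file.path(outdir, "filter_report.json"))
    state$filtered <<- filt
  })

  run_stage("biomarkers", function() {
    bm_args <- config$biomarkers
    res <- run_comparisons(state$filtered$matrix, state$cohort$metadata,
                           p_max = bm_args$p_max %||% 0.05,
                           auroc_min = bm_args$auroc_min %||% 0.7)
    write_biomarker_table(res, state$cohort$config$panel,
                          file.path(outdir, "biomarker_table.tsv"))
    qual <- res$qualified
    cormat <- correlation_matrix(
      state$filtered$matrix,
      antigens = if (length(qual) >= 2L) qual else NULL,
      labs = lab_matrix(state$cohort$metadata))
    utils::write.table(round(cormat, 10), file.path(outdir,
                                                    "correlation_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    cl <- hierarchical_cluster(state$filtered$matrix)
    jsonlite::write_json(list(sample_order = cl$sample_order,
                              antigen_order = cl$antigen_order,
                              settings = cl$settings),
                         file.path(outdir, "cluster_orders.json"),
                         auto_unbox = TRUE)
    state$biomarkers <<- res
  })

  run_stage("score", function() {
    transform <- config$score$transform %||% "identity"
    em <- state$filtered$matrix
    cls <- state$cohort$metadata$clinical_class[
      match(rownames(em$values), state$cohort$metadata$sample_id)]
    model <- sscore_model(em, cls, transform = transform)
    write_sscore_model(model, file.path(outdir, "sscore_model.json"))
    sc <- predict(model, em)
    sc$class <- cls
    utils::write.table(sc, file.path(outdir, "scores.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(score_cohort(model, em, cls),
                       file.path(outdir, "class_means.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    state$model <<- model
  })

  run_stage("evaluate", function() {
    ev <- config$evaluate
    B <- ev$B %||% 100L
    k <- ev$k %||% 3L
    em <- state$filtered$matrix
    md <- state$cohort$metadata
    cls <- md$clinical_class[match(rownames(em$values), md$sample_id)]
    cv <- cv_repeated_subsampling(em, cls, B = B, k = k,
                                  seed = config$seed)
    jsonlite::write_json(
      list(auroc_mean = as.list(cv$auroc_mean),
           auroc_sd = as.list(cv$auroc_sd),
           class_mean = as.list(cv$class_mean),
           class_sem = as.list(cv$class_sem),
           settings = cv$settings[c("B", "k", "seed", "rotate",
                                    "stratified")]),
      file.path(outdir, "cv_result.json"), auto_unbox = TRUE, digits = NA)
    iters <- data.frame(iteration = seq_len(nrow(cv$auroc)), cv$auroc,
                        check.names = FALSE)
    utils::write.table(iters, file.path(outdir, "cv_iterations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    state$cv <<- cv
    if (!isFALSE(ev$feature_sets)) {
      fsc <- feature_set_comparison(em, md, B = B, k = k,
                                    seed = config$seed)
      jsonlite::write_json(
        lapply(fsc$tasks, function(t) list(
          task = t$task, means = as.list(t$means),
          tests = t$tests)),
        file.path(outdir, "feature_set_comparison.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      state$feature_sets <<- fsc
    }
  })

  run_stage("report", function() {
    render_report(outdir)
  })

  files <- setdiff(list.files(outdir), c("manifest.json", "FAILED"))
  manifest <- list(
    package = "slescore",
    version = as.character(utils::packageVersion("slescore")),
    seed = config$seed,
    stages = config$stages,
    config_hash = config_hash(config),
    checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  state$manifest <- manifest
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_tsv_if <- function(path) {
  if (file.exists(path)) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else NULL
}

#' Render a plain-text run report
#'
#' Summarises the artifacts found in a run directory: filter counts, the
#' six-comparison biomarker table, per-class S-score means and the CV and
#' feature-set summaries. Sections whose stage outputs are absent are
#' replaced by a notice naming the stage to run. Every number is read back
#' from the stage output files, so the report is traceable to them.
#'
#' @param outdir a pipeline run directory
#' @return the report path, invisibly
#' @export
render_report <- function(outdir) {
  lines <- c("slescore pipeline report",
             "=========================", "")
  fr <- read_tsv_if(file.path(outdir, "filter_report.tsv"))
  if (is.null(fr)) {
    lines <- c(lines, "[preprocess] not run: no filter_report.tsv", "")
  } else {
    cap <- fr[fr$category == "capture", ]
    lines <- c(lines,
               sprintf("Quality filters: %d / %d capture antigens retained",
                       sum(cap$retained), nrow(cap)),
               sprintf("  failed low-expression: %d; failed SNR: %d",
                       sum(cap$reason == "low expression"),
                       sum(!cap$retained & cap$reason != "low expression")),
               "")
  }
  bm <- read_tsv_if(file.path(outdir, "biomarker_table.tsv"))
  if (is.null(bm)) {
    lines <- c(lines, "[biomarkers] not run: no biomarker_table.tsv", "")
  } else {
    qual <- bm[bm$qualified == "TRUE" | bm$qualified == TRUE, , drop = FALSE]
    lines <- c(lines,
               sprintf("Singleton biomarkers: %d qualified of %d screened",
                       nrow(qual), nrow(bm)),
               "  antigen  direction  best AUROC")
    if (nrow(qual) > 0L) {
      auc_cols <- grep("^auroc_", names(qual), value = TRUE)
      best <- apply(qual[, auc_cols, drop = FALSE], 1L, max, na.rm = TRUE)
      ord <- order(-best)
      lines <- c(lines, sprintf("  %-8s %-9s %.2f", qual$antigen[ord],
                                qual$direction[ord], best[ord]))
    }
    lines <- c(lines, "")
  }
  cmn <- read_tsv_if(file.path(outdir, "class_means.tsv"))
  if (is.null(cmn)) {
    lines <- c(lines, "[score] not run: no class_means.tsv", "")
  } else {
    lines <- c(lines, "Per-class mean S-score (full-cohort model):",
               sprintf("  %-13s n=%-3d mean %8.4f  sem %s", cmn$class,
                       cmn$n, cmn$mean_s,
                       ifelse(is.na(cmn$sem), "NA",
                              sprintf("%.4f", cmn$sem))),
               "")
  }
  cvp <- file.path(outdir, "cv_result.json")
  if (!file.exists(cvp)) {
    lines <- c(lines, "[evaluate] not run: no cv_result.json", "")
  } else {
    cv <- jsonlite::read_json(cvp, simplifyVector = TRUE)
    lines <- c(lines,
               sprintf("Cross-validation (%d iterations, %d folds):",
                       cv$settings$B, cv$settings$k),
               sprintf("  AUROC %-22s %.3f (sd %.3f)",
                       names(cv$auroc_mean), unlist(cv$auroc_mean),
                       unlist(cv$auroc_sd)),
               "  held-out per-class mean S-score:",
               sprintf("    %-13s %.4f (sem %.4f)", names(cv$class_mean),
                       unlist(cv$class_mean), unlist(cv$class_sem)),
               "")
    fsp <- file.path(outdir, "feature_set_comparison.json")
    if (file.exists(fsp)) {
      fs <- jsonlite::read_json(fsp, simplifyVector = TRUE)
      for (nm in names(fs)) {
        lines <- c(lines,
                   sprintf("Feature sets, %s: array %.3f | labs %.3f | combined %.3f",
                           nm, fs[[nm]]$means$array, fs[[nm]]$means$labs,
                           fs[[nm]]$means$combined),
                   sprintf("  %-18s one-sided paired p = %s %s",
                           fs[[nm]]$tests$hypothesis,
                           format.pval(fs[[nm]]$tests$p, digits = 3),
                           fs[[nm]]$tests$note))
      }
      lines <- c(lines, "")
    }
  }
  path <- file.path(outdir, "report.txt")
  writeLines(lines, path)
  invisible(path)
}
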
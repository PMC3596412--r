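#' Clinical class tokens
#'
#' The six clinical classes used throughout the package, ordered from healthy
#' through the SLE activity grades to the non-SLE disease controls. SLE
#' activity grades follow SLEDAI: inactive (SLEDAI <= 4), semi-active (5-7),
#' active (>= 8).
#'
#' @return character vector of class tokens
#' @export
clinical_classes <- function() {
  c("healthy", "sle_inactive", "sle_semi", "sle_active", "ra", "other_ai")
}

# SLE activity grade coding used by the generator and the ordering checks:
# healthy 0, inactive 1, semi-active 2, active 3; NA for ra / other_ai.
activity_grade <- function(class) {
  grades <- c(healthy = 0, sle_inactive = 1, sle_semi = 2, sle_active = 3,
              ra = NA, other_ai = NA)
  unname(grades[class])
}

#' Construct a raw slide
#'
#' A raw slide holds one sample's duplicate-spot intensities: exactly two
#' non-negative replicate values per panel feature, in arbitrary densitometry
#' units.
#'
#' @param sample_id sample identifier
#' @param intensities numeric matrix, one row per panel feature (rownames =
#'   feature ids), two columns (`rep1`, `rep2`)
#' @param panel the `antibody_panel` the slide was printed from
#' @return object of class `slide_raw`
#' @export
slide_raw <- function(sample_id, intensities, panel) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != 2L) {
    stop("slide '", sample_id, "': expected exactly two replicate columns")
  }
  if (is.null(rownames(intensities))) {
    stop("slide '", sample_id, "': intensity rows must be named by feature_id")
  }
  missing <- setdiff(panel$feature_id, rownames(intensities))
  if (length(missing) > 0L) {
    stop("slide '", sample_id, "': incomplete panel, missing feature(s): ",
         paste(missing, collapse = ", "))
  }
  unknown <- setdiff(rownames(intensities), panel$feature_id)
  if (length(unknown) > 0L) {
    stop("slide '", sample_id, "': feature(s) absent from panel: ",
         paste(unknown, collapse = ", "))
  }
  intensities <- intensities[panel$feature_id, , drop = FALSE]
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("slide '", sample_id, "': intensities must be finite and >= 0")
  }
  colnames(intensities) <- c("rep1", "rep2")
  structure(list(sample_id = sample_id, intensities = intensities),
            class = "slide_raw")
}

#' @export
print.slide_raw <- function(x, ...) {
  cat("Raw slide", x$sample_id, "-", nrow(x$intensities),
      "features x 2 replicates, max intensity",
      format(max(x$intensities), digits = 4), "\n")
  invisible(x)
}

#' Read duplicate-spot slides from tab-separated text
#'
#' Expected format (header required, `#` comment lines allowed):
#' `sample_id<TAB>feature_id<TAB>replicate_index<TAB>intensity` with
#' `replicate_index` in \{1, 2\}. Every sample must carry both replicates of
#' every panel feature.
#'
#' @param path file path
#' @param panel `antibody_panel` the slides must conform to
#' @return list of `slide_raw`, one per sample, in order of first appearance
#' @export
read_slides <- function(path, panel) {
  raw_lines <- readLines(path)
  keep <- !grepl("^\\s*#", raw_lines) & nzchar(trimws(raw_lines))
  line_no <- which(keep)
  if (length(line_no) < 1L) stop("empty slide file: ", path)
  fields <- strsplit(raw_lines[keep], "\t", fixed = TRUE)
  header <- fields[[1L]]
  expected <- c("sample_id", "feature_id", "replicate_index", "intensity")
  if (!identical(header, expected)) {
    stop("slide file header must be: ", paste(expected, collapse = ", "))
  }
  fields <- fields[-1L]
  line_no <- line_no[-1L]
  n_fields <- lengths(fields)
  if (any(n_fields != 4L)) {
    bad <- line_no[which(n_fields != 4L)[1L]]
    stop("malformed slide row at line ", bad, ": expected 4 tab-separated fields")
  }
  rec <- do.call(rbind, fields)
  rep_idx <- suppressWarnings(as.integer(rec[, 3L]))
  intensity <- suppressWarnings(as.numeric(rec[, 4L]))
  bad <- which(is.na(rep_idx) | !(rep_idx %in% c(1L, 2L)))
  if (length(bad) > 0L) {
    stop("parse failure at line ", line_no[bad[1L]],
         ": replicate_index must be 1 or 2 (got '", rec[bad[1L], 3L], "')")
  }
  bad <- which(is.na(intensity) | intensity < 0)
  if (length(bad) > 0L) {
    stop("parse failure at line ", line_no[bad[1L]],
         ": intensity must be a non-negative number (got '",
         rec[bad[1L], 4L], "')")
  }
  unknown <- setdiff(unique(rec[, 2L]), panel$feature_id)
  if (length(unknown) > 0L) {
    stop("completeness failure: feature(s) not in panel: ",
         paste(unknown, collapse = ", "))
  }
  sample_ids <- unique(rec[, 1L])
  lapply(sample_ids, function(sid) {
    rows <- rec[, 1L] == sid
    m <- matrix(NA_real_, nrow = nrow(panel), ncol = 2L,
                dimnames = list(panel$feature_id, c("rep1", "rep2")))
    m[cbind(match(rec[rows, 2L], rownames(m)), rep_idx[rows])] <-
      intensity[rows]
    if (anyNA(m)) {
      miss <- rownames(m)[which(rowSums(is.na(m)) > 0L)]
      stop("completeness failure: sample '", sid,
           "' is missing replicate(s) for: ", paste(miss, collapse = ", "))
    }
    slide_raw(sid, m, panel)
  })
}

#' @rdname read_slides
#' @param slides list of `slide_raw`
#' @param header_lines optional character vector of provenance lines written
#'   as `#`-prefixed comments before the header
#' @export
write_slides <- function(slides, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0("# ", header_lines), con)
  }
  writeLines("sample_id\tfeature_id\treplicate_index\tintensity", con)
  for (sl in slides) {
    fid <- rownames(sl$intensities)
    for (r in 1:2) {
      writeLines(sprintf("%s\t%s\t%d\t%s", sl$sample_id, fid, r,
                         format(sl$intensities[, r], digits = 15,
                                scientific = FALSE, trim = TRUE)), con)
    }
  }
  invisible(path)
}

#' Assign an SLE activity class from a SLEDAI score
#'
#' SLEDAI >= 8 is clinically active, 5-7 semi-active (intermediate), <= 4
#' inactive.
#'
#' @param sledai non-negative integer SLEDAI score (vectorised)
#' @return character vector of class tokens
#' @export
assign_activity_class <- function(sledai) {
  if (any(is.na(sledai)) || any(sledai < 0) || any(sledai != round(sledai))) {
    stop("sledai must be a non-negative integer")
  }
  ifelse(sledai >= 8, "sle_active",
         ifelse(sledai >= 5, "sle_semi", "sle_inactive"))
}

validate_metadata <- function(df) {
  required <- c("sample_id", "clinical_class", "sledai", "dsdna_positive",
                "c3", "c4")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("metadata missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, required]
  bad <- setdiff(unique(df$clinical_class), clinical_classes())
  if (length(bad) > 0L) {
    stop("unknown clinical_class token(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in metadata")
  has_sledai <- !is.na(df$sledai)
  sle <- df$clinical_class %in% c("sle_inactive", "sle_semi", "sle_active")
  chk <- has_sledai & sle
  if (any(chk)) {
    implied <- assign_activity_class(df$sledai[chk])
    off <- which(implied != df$clinical_class[chk])
    if (length(off) > 0L) {
      i <- which(chk)[off[1L]]
      stop("metadata consistency failure: sample '", df$sample_id[i],
           "' has sledai=", df$sledai[i], " but clinical_class '",
           df$clinical_class[i], "' (implies '",
           assign_activity_class(df$sledai[i]), "')")
    }
  }
  if (!all(df$dsdna_positive %in% c(0L, 1L, NA))) {
    stop("dsdna_positive must be 0, 1 or empty")
  }
  rownames(df) <- NULL
  df
}

#' Read / write sample metadata
#'
#' Tab-separated with header
#' `sample_id<TAB>clinical_class<TAB>sledai<TAB>dsdna_positive<TAB>c3<TAB>c4`;
#' empty cells denote absent lab values; `#` comment lines allowed. SLEDAI
#' (when present for an SLE sample) must be consistent with the activity
#' class thresholds.
#'
#' @param path file path
#' @return data frame with one row per sample
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  df$sample_id <- as.character(df$sample_id)
  df$sledai <- as.integer(df$sledai)
  df$dsdna_positive <- as.integer(df$dsdna_positive)
  df$c3 <- as.numeric(df$c3)
  df$c4 <- as.numeric(df$c4)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata metadata data frame
#' @param header_lines optional `#`-prefixed provenance lines
#' @export
write_metadata <- function(metadata, path, header_lines = NULL) {
  metadata <- validate_metadata(metadata)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  out <- metadata
  out$c3 <- ifelse(is.na(out$c3), "", format(out$c3, digits = 15, trim = TRUE))
  out$c4 <- ifelse(is.na(out$c4), "", format(out$c4, digits = 15, trim = TRUE))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Ingest a GEO series-matrix file
#'
#' Best-effort import of a locally downloaded series-matrix text file (the
#' SOFT-derived format GEO serves for a series such as GSE27293). Values in
#' a series matrix are typically already processed, so the result is an
#' expression table plus sample annotations rather than raw duplicate-spot
#' slides; the returned provenance records that the values are taken as
#' already normalized and which probes could not be mapped onto the panel.
#'
#' @param path path to a `*_series_matrix.txt` file
#' @param panel_mapping named character vector mapping platform probe ids
#'   (the series-matrix ID_REF values) to panel feature ids; probes absent
#'   from the mapping are reported unmapped and dropped
#' @return list with `values` (samples x features matrix), `sample_info`
#'   (data frame of `!Sample_*` annotation lines), `unmapped` (character),
#'   and `provenance` (list; includes `values_are_normalized = TRUE`)
#' @export
ingest_geo_series <- function(path, panel_mapping) {
  if (!file.exists(path)) stop("series-matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    stop("malformed series matrix: missing table delimiters")
  }
  ann_lines <- grep("^!Sample_", lines, value = TRUE)
  ann <- lapply(strsplit(ann_lines, "\t"), function(f) gsub('^"|"$', "", f))
  sample_info <- NULL
  if (length(ann) > 0L) {
    keys <- vapply(ann, function(f) sub("^!Sample_", "", f[[1L]]), "")
    vals <- lapply(ann, function(f) f[-1L])
    nmax <- max(lengths(vals))
    vals <- lapply(vals, function(v) c(v, rep(NA, nmax - length(v))))
    sample_info <- as.data.frame(stats::setNames(vals, make.unique(keys)),
                                 stringsAsFactors = FALSE,
                                 check.names = FALSE)
  }
  tab <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                           header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  probe <- gsub('^"|"$', "", as.character(tab[[1L]]))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  mode(vals) <- "numeric"
  rownames(vals) <- probe
  unmapped <- setdiff(probe, names(panel_mapping))
  if (length(unmapped) > 0L) {
    warning("unmapped probe(s) dropped: ", paste(unmapped, collapse = ", "))
  }
  mapped <- intersect(probe, names(panel_mapping))
  vals <- vals[mapped, , drop = FALSE]
  rownames(vals) <- unname(panel_mapping[mapped])
  list(values = t(vals),
       sample_info = sample_info,
       unmapped = unmapped,
       provenance = list(source = path,
                         values_are_normalized = TRUE,
                         n_samples = ncol(vals),
                         n_mapped = length(mapped)))
}
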
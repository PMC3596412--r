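#' Antibody panel constructor
#'
#' An antibody panel describes the features printed on a leukocyte-capture
#' slide: the capture antibodies directed against CD antigens, isotype-control
#' spots measuring non-specific binding, and anchor spots (anti-CD44) marking
#' the array perimeter.
#'
#' @param features data frame with columns `feature_id`, `label`, `category`
#'   (one of `"capture"`, `"isotype_control"`, `"anchor"`) and `lineage`
#'   (one of `"T"`, `"NK"`, `"B"`, `"other"`).
#' @return An object of class `antibody_panel` (a validated data frame).
#' @export
antibody_panel <- function(features) {
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  required <- c("feature_id", "label", "category", "lineage")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0L) {
    stop("panel is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  features <- features[, required]
  if (anyDuplicated(features$feature_id)) {
    dup <- unique(features$feature_id[duplicated(features$feature_id)])
    stop("duplicated feature_id in panel: ", paste(dup, collapse = ", "))
  }
  bad_cat <- setdiff(unique(features$category),
                     c("capture", "isotype_control", "anchor"))
  if (length(bad_cat) > 0L) {
    stop("unknown panel category: ", paste(bad_cat, collapse = ", "))
  }
  if (!any(features$category == "capture")) {
    stop("panel must contain at least one capture feature")
  }
  bad_lin <- setdiff(unique(features$lineage), c("T", "NK", "B", "other"))
  if (length(bad_lin) > 0L) {
    stop("unknown lineage tag: ", paste(bad_lin, collapse = ", "))
  }
  rownames(features) <- NULL
  class(features) <- c("antibody_panel", "data.frame")
  features
}

#' Default 82-antibody leukocyte-capture panel
#'
#' Returns the package's default panel: 82 capture antibodies against
#' leukocyte surface antigens (T-, NK- and B-cell lineage markers plus a
#' broad myeloid/activation complement), three isotype-control spots and the
#' anti-CD44 perimeter anchor. The capture set includes all antigens reported
#' as activity-associated on first-generation leukocyte-capture arrays
#' (TCR a/b, CD2-CD8, CD28, CD45RA, CD56, CD57, CD52, kappa and lambda light
#' chains, CD66c, CD95).
#'
#' @return An `antibody_panel` with 86 features (82 capture).
#' @export
default_panel <- function() {
  t_markers  <- c("TCRab", "TCRgd", "CD2", "CD3", "CD4", "CD5", "CD7", "CD8",
                  "CD28", "CD45RA", "CD45RO", "CD25")
  nk_markers <- c("CD56", "CD57", "CD16")
  b_markers  <- c("kappa", "lambda", "CD19", "CD20", "CD21", "CD22", "CD23",
                  "CD24", "CD10", "CD38", "CD79b", "FMC7", "sIgM")
  other <- c("CD52", "CD66c", "CD95", "CD1a", "CD9", "CD11a", "CD11b",
             "CD11c", "CD13", "CD14", "CD15", "CD18", "CD29", "CD31",
             "CD32", "CD33", "CD34", "CD36", "CD37", "CD40", "CD41",
             "CD42a", "CD43", "CD45", "CD49d", "CD54", "CD55", "CD59",
             "CD61", "CD62E", "CD62L", "CD62P", "CD63", "CD64", "CD66b",
             "CD69", "CD71", "CD86", "CD95L", "CD98", "CD102", "CD103",
             "CD117", "CD122", "CD126", "CD128", "CD130", "CD134",
             "CD138", "CD154", "CD235a", "HLA-DR", "HLA-ABC", "CD49e")
  labels <- c(t_markers, nk_markers, b_markers, other)
  stopifnot(length(labels) == 82L)
  lineage <- c(rep("T", length(t_markers)), rep("NK", length(nk_markers)),
               rep("B", length(b_markers)), rep("other", length(other)))
  features <- data.frame(
    feature_id = labels,
    label = labels,
    category = "capture",
    lineage = lineage,
    stringsAsFactors = FALSE
  )
  controls <- data.frame(
    feature_id = c("IgG1-iso", "IgG2a-iso", "IgM-iso", "CD44"),
    label = c("IgG1 isotype", "IgG2a isotype", "IgM isotype", "CD44"),
    category = c(rep("isotype_control", 3L), "anchor"),
    lineage = "other",
    stringsAsFactors = FALSE
  )
  antibody_panel(rbind(features, controls))
}

#' @export
print.antibody_panel <- function(x, ...) {
  n <- table(factor(x$category,
                    levels = c("capture", "isotype_control", "anchor")))
  cat("Antibody panel:", nrow(x), "features (",
      n[["capture"]], "capture,", n[["isotype_control"]],
      "isotype control,", n[["anchor"]], "anchor )\n")
  invisible(x)
}

#' Feature ids of the capture antibodies in a panel
#' @param panel an `antibody_panel`
#' @return character vector of feature ids
#' @export
capture_features <- function(panel) {
  panel$feature_id[panel$category == "capture"]
}

#' Read / write a panel as tab-separated text
#'
#' Format: `feature_id<TAB>label<TAB>category<TAB>lineage`, header row
#' required, lines starting with `#` ignored.
#'
#' @param path file path
#' @return `read_panel` returns an `antibody_panel`; `write_panel` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  antibody_panel(df)
}

#' @rdname read_panel
#' @param panel an `antibody_panel`
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
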
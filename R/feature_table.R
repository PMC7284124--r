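#' Construct a subjects-by-ROI feature table
#'
#' A thin validated container for one cortical parameter (thickness in mm or
#' surface area in mm^2) measured on every region of one parcellation. Rows
#' are subjects, columns are ROIs.
#'
#' @param values Numeric matrix, subjects in rows and ROIs in columns. Must
#'   carry unique row names (subject IDs) and column names (ROI IDs) and
#'   contain no missing or non-finite values.
#' @param parameter Which cortical parameter the values are, `"CT"`
#'   (cortical thickness) or `"SA"` (surface area).
#' @param atlas_id Label of the parcellation the ROIs come from.
#'
#' @return An object of class `feature_table`: the matrix with `parameter`
#'   and `atlas_id` attributes.
#' @export
feature_table <- function(values, parameter = c("CT", "SA"), atlas_id = "atlas") {
  parameter <- match.arg(parameter)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("`values` must have unique row names (subject IDs)")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` must have unique column names (ROI IDs)")
  if (any(!is.finite(values)))
    stop("feature table contains missing or non-finite values")
  structure(values, parameter = parameter, atlas_id = atlas_id,
            class = c("feature_table", "matrix", "array"))
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d subjects x %d ROIs (%s, atlas '%s')\n",
              nrow(x), ncol(x), attr(x, "parameter"), attr(x, "atlas_id")))
  invisible(x)
}

# Coerce matrix-like input, preserving attributes when already a feature_table.
as_feature_matrix <- function(x) {
  if (inherits(x, "feature_table")) return(x)
  if (!is.matrix(x)) stop("features must be a matrix or feature_table")
  x
}

#' Write a cohort to TSV files
#'
#' @param features A [feature_table()].
#' @param records Subject metadata data frame (one row per subject, first
#'   column `subject_id`).
#' @param feature_path,metadata_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(features, records, feature_path, metadata_path) {
  df <- data.frame(subject_id = rownames(features),
                   as.data.frame(unclass(features)[, , drop = FALSE]),
                   check.names = FALSE)
  write.table(df, feature_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(records, metadata_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(feature_path, metadata_path))
}

#' Read a cohort from TSV files
#'
#' Reads the feature table and subject metadata written by [write_cohort()]
#' (or prepared externally in the same layout), aligns subject order between
#' the two, and validates both. All validation failures are aggregated and
#' reported together.
#'
#' @param feature_path TSV with header `subject_id` followed by ROI IDs.
#' @param metadata_path TSV with header `subject_id, group,
#'   primary_diagnosis, dual_diagnosis, age, handedness, ...`.
#' @param parameter,atlas_id Passed to [feature_table()].
#' @return A list with elements `features` (a `feature_table`) and `records`
#'   (a data frame), subject order aligned.
#' @export
read_cohort <- function(feature_path, metadata_path,
                        parameter = c("CT", "SA"), atlas_id = "atlas") {
  parameter <- match.arg(parameter)
  feat <- read.delim(feature_path, check.names = FALSE, colClasses = "character")
  meta <- read.delim(metadata_path, check.names = FALSE)
  errs <- character()
  if (names(feat)[1] != "subject_id")
    errs <- c(errs, "feature file: first column must be 'subject_id'")
  if (!"subject_id" %in% names(meta))
    errs <- c(errs, "metadata file: missing 'subject_id' column")
  if (length(errs)) stop(paste(errs, collapse = "\n  "))

  ids <- feat$subject_id
  if (anyDuplicated(ids))
    errs <- c(errs, sprintf("duplicate subject IDs in feature file: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (anyDuplicated(meta$subject_id))
    errs <- c(errs, sprintf("duplicate subject IDs in metadata: %s",
                            paste(unique(meta$subject_id[duplicated(meta$subject_id)]), collapse = ", ")))
  only_feat <- setdiff(ids, meta$subject_id)
  only_meta <- setdiff(meta$subject_id, ids)
  if (length(only_feat))
    errs <- c(errs, sprintf("subjects only in feature file: %s", paste(only_feat, collapse = ", ")))
  if (length(only_meta))
    errs <- c(errs, sprintf("subjects only in metadata: %s", paste(only_meta, collapse = ", ")))

  vals <- as.matrix(feat[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(!is.finite(num) , arr.ind = TRUE)
  if (nrow(bad)) {
    for (r in seq_len(min(nrow(bad), 10L)))
      errs <- c(errs, sprintf("non-numeric feature cell at subject '%s', ROI '%s'",
                              ids[bad[r, 1]], colnames(num)[bad[r, 2]]))
  }
  if (length(errs)) stop(paste(c("cohort validation failed:", errs), collapse = "\n  "))

  meta <- meta[match(ids, meta$subject_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(features = feature_table(num, parameter, atlas_id), records = meta)
}
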
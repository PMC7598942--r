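#' Subject-level feature table
#'
#' The central data container: one row per subject, holding identifiers,
#' site membership, diagnosis, demographic covariates, optional clinical
#' variables, and an ordered vector of named regional brain measures
#' (cortical thickness in mm, surface area in mm^2, volumes in mm^3).
#' Missing feature cells are tracked explicitly in a logical mask; the
#' feature matrix carries `NA` at masked cells.
#'
#' @param meta data.frame with columns `subject_id` (unique character),
#'   `site_id`, `diagnosis` (0 = control, 1 = case), `age` (years), `sex`,
#'   and optionally `medicated` (0/1), `ybocs` (non-negative integer),
#'   `age_of_onset` (years) and `illness_duration` (years).  Clinical
#'   columns may be `NA` (always so for controls).
#' @param features numeric matrix, one row per subject, named columns in a
#'   fixed order shared by all rows.
#' @param mask logical matrix of the same shape; `TRUE` marks a missing
#'   cell.  Defaults to `is.na(features)`.
#' @return an object of class `subject_table`.
#' @seealso [read_subject_table()], [write_subject_table()],
#'   [generate_cohort()]
#' @export
subject_table <- function(meta, features, mask = is.na(features)) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  rownames(features) <- NULL
  mask <- as.matrix(mask)
  dimnames(mask) <- dimnames(features)
  x <- structure(list(meta = meta, features = features, mask = mask),
                 class = "subject_table")
  validate_subject_table(x)
  x
}

#' Validate a subject table
#'
#' Checks the structural invariants: unique subject ids, a site and a 0/1
#' diagnosis for every row, a named feature matrix aligned with the mask,
#' and masked cells stored as `NA`.
#'
#' @param x a [subject_table()].
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_subject_table <- function(x) {
  stopifnot(inherits(x, "subject_table"))
  m <- x$meta
  req <- c("subject_id", "site_id", "diagnosis")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(m$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(m$subject_id[duplicated(m$subject_id)]), collapse = ", "))
  if (any(is.na(m$site_id)) || any(is.na(m$diagnosis)))
    stop("site_id and diagnosis must be present for every row")
  bad <- !m$diagnosis %in% c(0, 1)
  if (any(bad))
    stop("diagnosis must be coded 0/1; offending rows: ",
         paste(which(bad), collapse = ", "))
  if (nrow(x$features) != nrow(m))
    stop("feature matrix and meta table have different row counts")
  if (is.null(colnames(x$features)))
    stop("feature columns must be named")
  if (anyDuplicated(colnames(x$features)))
    stop("duplicate feature names")
  if (!identical(dim(x$mask), dim(x$features)))
    stop("mask and feature matrix shapes differ")
  if (any(x$mask & !is.na(x$features)))
    stop("masked cells must hold NA in the feature matrix")
  if (any(is.na(x$features) & !x$mask))
    stop("NA feature cells must be flagged in the mask")
  invisible(x)
}

#' @export
print.subject_table <- function(x, ...) {
  cat(sprintf("subject_table: %d subjects, %d sites, %d features\n",
              nrow(x$meta), length(unique(x$meta$site_id)),
              ncol(x$features)))
  cat(sprintf("  cases %d / controls %d; %.2f%% feature cells missing\n",
              sum(x$meta$diagnosis == 1), sum(x$meta$diagnosis == 0),
              100 * mean(x$mask)))
  invisible(x)
}

#' Number of subjects / feature names
#' @param x a [subject_table()].
#' @return `n_subjects()` the row count; `feature_names()` the ordered
#'   feature-column names.
#' @export
n_subjects <- function(x) nrow(x$meta)

#' @rdname n_subjects
#' @export
feature_names <- function(x) colnames(x$features)

#' Row-subset a subject table
#' @param x a [subject_table()].
#' @param i integer or logical row index.
#' @return a `subject_table` with the selected rows, order preserved.
#' @export
subset_table <- function(x, i) {
  subject_table(x$meta[i, , drop = FALSE],
                x$features[i, , drop = FALSE],
                x$mask[i, , drop = FALSE])
}

.meta_cols <- c("subject_id", "site_id", "diagnosis", "age", "sex",
                "medicated", "ybocs", "age_of_onset", "illness_duration")

#' Read a subject table from delimited text
#'
#' Accepts comma- or tab-separated files (the delimiter is auto-detected
#' from the header line); empty cells and the token `"NA"` are treated as
#' missing.  Columns are matched by a schema map from canonical names to
#' file column names; every column not claimed by the schema is taken to be
#' a brain feature, in file order.
#'
#' @param path file path.
#' @param schema named character vector mapping canonical column names
#'   (`subject_id`, `site_id`, `diagnosis`, `age`, `sex`, `medicated`,
#'   `ybocs`, `age_of_onset`, `illness_duration`) to the names used in the
#'   file.  Defaults to the identity map; clinical entries are optional.
#' @return a [subject_table()] with missing feature cells recorded in the
#'   mask and row order preserved.
#' @export
read_subject_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character(0), quote = "\"",
                          comment.char = "")
  full <- stats::setNames(.meta_cols, .meta_cols)
  if (!is.null(schema)) full[names(schema)] <- schema
  req <- c("subject_id", "site_id", "diagnosis")
  for (cn in req)
    if (!full[[cn]] %in% names(df))
      stop("schema error: required column '", full[[cn]],
           "' (", cn, ") not found in ", path)
  present <- full[full %in% names(df)]
  meta <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                     subject_id = df[[present[["subject_id"]]]])
  is_missing <- function(v) v == "" | v == "NA"
  num_or_na <- function(v, what) {
    out <- rep(NA_real_, length(v))
    obs <- !is_missing(v)
    x <- suppressWarnings(as.numeric(v[obs]))
    if (anyNA(x)) {
      bad <- which(obs)[is.na(x)][1L]
      stop("parse error: non-numeric value '", v[bad], "' in column '",
           what, "', row ", bad)
    }
    out[obs] <- x
    out
  }
  meta$site_id <- df[[present[["site_id"]]]]
  dx <- df[[present[["diagnosis"]]]]
  bad <- which(!dx %in% c("0", "1"))
  if (length(bad))
    stop("validation error: diagnosis column contains values other than ",
         "0/1 in rows: ", paste(bad, collapse = ", "))
  meta$diagnosis <- as.integer(dx)
  for (cn in c("age", "sex", "medicated", "ybocs", "age_of_onset",
               "illness_duration")) {
    if (!cn %in% names(present)) next
    v <- df[[present[[cn]]]]
    meta[[cn]] <- if (cn == "sex") {
      ifelse(is_missing(v), NA_character_, v)
    } else num_or_na(v, present[[cn]])
  }
  feat_cols <- setdiff(names(df), unname(present))
  feats <- matrix(NA_real_, nrow(df), length(feat_cols),
                  dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols))
    feats[, j] <- num_or_na(df[[feat_cols[j]]], feat_cols[j])
  subject_table(meta, feats)
}

#' Write a subject table as tab-separated text
#'
#' Serialises meta columns followed by the feature columns in their stored
#' order; missing cells are written as `NA`.  [read_subject_table()] on the
#' output reproduces the table values exactly.
#'
#' @param x a [subject_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(x, path) {
  validate_subject_table(x)
  meta <- x$meta[, intersect(.meta_cols, names(x$meta)), drop = FALSE]
  out <- cbind(meta, as.data.frame(x$features, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
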
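#' Construct a descriptor table
#'
#' A descriptor table holds one row per compound and one numeric column per
#' molecular descriptor, with an optional per-compound bioactivity target
#' (pIC50, in -log10 molar units). It is the container every pipeline stage
#' consumes and returns.
#'
#' @param values numeric matrix, compounds in rows, descriptors in columns;
#'   must carry unique column names. Missing values are allowed before
#'   cleaning.
#' @param compound_ids character vector of compound identifiers, one per row.
#'   Defaults to the matrix rownames, or `cmpd_<i>` when absent.
#' @param target optional numeric vector of pIC50 values, one per compound.
#'
#' @return An object of class `descriptor_table`: a list with elements
#'   `compound_ids`, `values` and `target`.
#' @export
descriptor_table <- function(values, compound_ids = NULL, target = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("descriptor_table: 'values' must be a numeric matrix")
  if (is.null(colnames(values)))
    stop("descriptor_table: 'values' must have column names")
  if (anyDuplicated(colnames(values)))
    stop("descriptor_table: descriptor names must be unique")
  if (is.null(compound_ids)) {
    compound_ids <- rownames(values)
    if (is.null(compound_ids))
      compound_ids <- paste0("cmpd_", seq_len(nrow(values)))
  }
  compound_ids <- as.character(compound_ids)
  if (length(compound_ids) != nrow(values))
    stop("descriptor_table: one compound id per row required")
  if (!is.null(target)) {
    target <- as.numeric(target)
    if (length(target) != nrow(values))
      stop("descriptor_table: target length must equal number of compounds")
  }
  rownames(values) <- NULL
  structure(
    list(compound_ids = compound_ids, values = values, target = target),
    class = "descriptor_table"
  )
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("descriptor_table: ", length(x$compound_ids), " compounds x ",
      ncol(x$values), " descriptors",
      if (!is.null(x$target)) " (+ pIC50 target)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' Descriptor names of a table
#' @param table a `descriptor_table`.
#' @return Character vector of descriptor (column) names.
#' @export
descriptor_names <- function(table) colnames(table$values)

#' Subset a descriptor table by descriptor name
#'
#' @param table a `descriptor_table`.
#' @param keep character vector of descriptor names to retain.
#' @return A `descriptor_table` restricted to `keep` (target preserved).
#' @export
select_descriptors <- function(table, keep) {
  stopifnot(inherits(table, "descriptor_table"))
  missing <- setdiff(keep, descriptor_names(table))
  if (length(missing))
    stop("select_descriptors: unknown descriptors: ",
         paste(missing, collapse = ", "))
  descriptor_table(table$values[, keep, drop = FALSE],
                   compound_ids = table$compound_ids,
                   target = table$target)
}

#' Read a descriptor table from CSV
#'
#' Expected dialect: comma-separated with a header row; first column
#' `compound_id`; an optional target column (default name `pIC50`); every
#' other column a numeric descriptor.
#'
#' @param path CSV file path.
#' @param target_col name of the target column, or `NULL` for none.
#' @return A `descriptor_table`.
#' @export
read_descriptor_table <- function(path, target_col = "pIC50") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"compound_id" %in% names(df))
    stop("read_descriptor_table: first column must be 'compound_id'")
  ids <- as.character(df$compound_id)
  df$compound_id <- NULL
  target <- NULL
  if (!is.null(target_col) && target_col %in% names(df)) {
    target <- as.numeric(df[[target_col]])
    df[[target_col]] <- NULL
  }
  descriptor_table(as.matrix(df), compound_ids = ids, target = target)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]: `compound_id` first, then the
#' target column (if any), then the descriptors.
#'
#' @param table a `descriptor_table`.
#' @param path output CSV path.
#' @param target_col column name used for the target when present.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path, target_col = "pIC50") {
  stopifnot(inherits(table, "descriptor_table"))
  df <- data.frame(compound_id = table$compound_ids, check.names = FALSE)
  if (!is.null(table$target)) df[[target_col]] <- table$target
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validate a binary endpoint label table
#'
#' A label table is a data frame whose first column is `compound_id` and
#' whose remaining columns are binary (0/1) ADMET endpoints with no missing
#' values, in the same compound order as the descriptor table they annotate.
#'
#' @param labels data frame of labels.
#' @param table optional `descriptor_table` to check compound order against.
#' @return `labels`, invisibly, after validation.
#' @export
validate_label_table <- function(labels, table = NULL) {
  if (!is.data.frame(labels) || names(labels)[1] != "compound_id")
    stop("label table: first column must be 'compound_id'")
  ep <- labels[, -1, drop = FALSE]
  if (ncol(ep) < 1) stop("label table: no endpoint columns")
  ok <- vapply(ep, function(v) !anyNA(v) && all(v %in% c(0, 1)), logical(1))
  if (!all(ok))
    stop("label table: non-binary or missing values in: ",
         paste(names(ep)[!ok], collapse = ", "))
  if (!is.null(table) &&
      !identical(as.character(labels$compound_id), table$compound_ids))
    stop("label table: compound order differs from descriptor table")
  invisible(labels)
}
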
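#' Construct a feature matrix with an optional class label
#'
#' A `feature_matrix` is the container every imputer and evaluation routine
#' in this package operates on: a numeric matrix of observations by features
#' in which `NA` marks a missing cell, plus an optional class-label vector
#' that is never imputed and never allowed to contain missing entries.
#'
#' @param x numeric matrix or data frame of feature values; `NA` marks a
#'   missing cell. All entries must be finite or `NA`.
#' @param label optional vector of class labels, one per row; must be
#'   complete (no `NA`).
#' @param label_name column name used for the label when the object is
#'   written to or read from CSV.
#' @return an object of class `feature_matrix` with components `x` (numeric
#'   matrix), `label` (factor or `NULL`) and `label_name`.
#' @examples
#' fm <- feature_matrix(matrix(c(1, NA, 3, 4), 2, 2), label = c("a", "b"))
#' n_missing(fm)
#' @export
feature_matrix <- function(x, label = NULL, label_name = "class") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix or data frame", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop("feature matrix must have at least one row and one column",
         call. = FALSE)
  }
  if (any(is.infinite(x)) || any(is.nan(x))) {
    stop("feature cells must be finite numbers or NA", call. = FALSE)
  }
  if (is.null(colnames(x))) {
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  }
  if (!is.null(label)) {
    if (length(label) != nrow(x)) {
      stop("`label` must have one entry per row", call. = FALSE)
    }
    if (anyNA(label)) {
      stop("the label column must not contain missing values", call. = FALSE)
    }
    label <- factor(label)
  }
  structure(list(x = x, label = label, label_name = label_name),
            class = "feature_matrix")
}

#' Coerce a data frame to a feature matrix
#'
#' @param df data frame whose non-label columns are numeric features.
#' @param label_column name of the class-label column in `df`, or `NULL`
#'   for an unlabelled matrix.
#' @param label_name name to carry for the label column (defaults to
#'   `label_column` when given).
#' @return a [feature_matrix()].
#' @export
as_feature_matrix <- function(df, label_column = NULL, label_name = NULL) {
  stopifnot(is.data.frame(df))
  label <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% names(df)) {
      stop("label column '", label_column, "' not found in input",
           call. = FALSE)
    }
    label <- df[[label_column]]
    df <- df[setdiff(names(df), label_column)]
    if (is.null(label_name)) label_name <- label_column
  }
  if (is.null(label_name)) label_name <- "class"
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) {
    stop("non-numeric feature column(s): ",
         paste(names(df)[!num], collapse = ", "), call. = FALSE)
  }
  feature_matrix(as.matrix(df), label = label, label_name = label_name)
}

#' @export
as.data.frame.feature_matrix <- function(x, ...) {
  df <- as.data.frame(x$x)
  if (!is.null(x$label)) df[[x$label_name]] <- x$label
  df
}

#' @export
dim.feature_matrix <- function(x) dim(x$x)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d observations x %d features, %d missing cell(s)%s\n",
              nrow(x$x), ncol(x$x), sum(is.na(x$x)),
              if (is.null(x$label)) "" else
                sprintf(", label '%s' (%d classes)", x$label_name,
                        nlevels(x$label))))
  invisible(x)
}

#' Count missing feature cells
#' @param fm a [feature_matrix()].
#' @return integer count of `NA` feature cells.
#' @export
n_missing <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  sum(is.na(fm$x))
}

#' Logical mask of missing feature cells
#' @param fm a [feature_matrix()].
#' @return logical matrix, `TRUE` where the feature cell is missing.
#' @export
missing_mask <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  is.na(fm$x)
}

#' Read a delimited-text dataset into a feature matrix
#'
#' Comma-delimited with a header row; configurable missing-value markers
#' (the defaults cover empty cells, `NA`, and the `?` convention used by
#' several public machine-learning datasets).
#'
#' @param path CSV file path.
#' @param label_column optional name of the class-label column.
#' @param missing character vector of cell contents to read as missing.
#' @return a [feature_matrix()].
#' @export
read_feature_csv <- function(path, label_column = NULL,
                             missing = c("", "NA", "?")) {
  df <- utils::read.csv(path, na.strings = missing, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!is.null(label_column) && label_column %in% names(df) &&
      anyNA(df[[label_column]])) {
    stop("the label column must not contain missing values", call. = FALSE)
  }
  as_feature_matrix(df, label_column = label_column)
}

#' Write a feature matrix to CSV
#'
#' @param fm a [feature_matrix()].
#' @param path output file path.
#' @param missing marker written for missing cells (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path, missing = "NA") {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm)
  utils::write.csv(df, path, row.names = FALSE, na = missing)
  invisible(path)
}

#' The five-row illustration grid
#'
#' A small six-column numeric grid with one missing cell at row 3, column A,
#' used throughout the documentation and tests to walk the fuzzy
#' nearest-neighbor imputation through by hand: with `k = 3` the complete
#' rows closest to row 3 carry the column-A values 2, 1 and 7, the
#' triangular weighted average restores 2, and the Gaussian weighted average
#' restores about 2.63.
#'
#' @return a [feature_matrix()] with columns A-F and no label.
#' @examples
#' impute_cell(demo_grid(), 3, 1, imputer_config(k = 3))
#' @export
demo_grid <- function() {
  x <- matrix(c(
     2,  0, 100, 0.2, 2, 0,
     5, 51, 400, 0.7, 0, 1,
    NA, 23, 100, 0.9, 3, 0,
     7,  0, 200, 0.8, 5, 1,
     1, 11,   0, 0.1, 4, 0),
    nrow = 5, byrow = TRUE,
    dimnames = list(NULL, c("A", "B", "C", "D", "E", "F")))
  feature_matrix(x)
}
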
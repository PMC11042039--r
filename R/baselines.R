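#' Column-mean imputation
#'
#' Replaces each missing feature cell by the arithmetic mean of the
#' observed values in its column. Observed cells are unchanged.
#'
#' @param fm a [feature_matrix()]; every feature column must have at least
#'   one observed value.
#' @return a complete [feature_matrix()].
#' @export
mean_impute <- function(fm) {
  column_impute(fm, function(v) mean(v))
}

#' Column-median imputation
#'
#' As [mean_impute()], with the column median (midpoint of the two central
#' order statistics for an even count of observed values).
#'
#' @inheritParams mean_impute
#' @return a complete [feature_matrix()].
#' @export
median_impute <- function(fm) {
  column_impute(fm, function(v) stats::median(v))
}

column_impute <- function(fm, fun) {
  stopifnot(inherits(fm, "feature_matrix"))
  out <- fm
  for (j in seq_len(ncol(fm$x))) {
    miss <- is.na(fm$x[, j])
    if (!any(miss)) next
    obs <- fm$x[!miss, j]
    if (length(obs) == 0L) {
      stop("column ", colnames(fm$x)[j], " is entirely missing",
           call. = FALSE)
    }
    out$x[miss, j] <- fun(obs)
  }
  out
}

#' Listwise deletion
#'
#' Drops every observation that has at least one missing feature cell,
#' preserving row order.
#'
#' @param fm a [feature_matrix()].
#' @return a [feature_matrix()] containing only the complete rows; an
#'   error if no complete row remains.
#' @export
listwise_delete <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  keep <- rowSums(is.na(fm$x)) == 0L
  if (!any(keep)) stop("listwise deletion removed every row", call. = FALSE)
  out <- fm
  out$x <- fm$x[keep, , drop = FALSE]
  if (!is.null(fm$label)) out$label <- fm$label[keep]
  out
}

#' Apply a named missing-data handler
#'
#' Dispatch helper used by the benchmark and the command line: `"triangular"`
#' and `"gaussian"` run [impute_matrix()] with the corresponding membership,
#' `"mean"`, `"median"` and `"listwise"` run the conventional baselines, and
#' `"none"` returns the input unchanged.
#'
#' @param fm a [feature_matrix()].
#' @param method one of `"triangular"`, `"gaussian"`, `"mean"`, `"median"`,
#'   `"listwise"`, `"none"`.
#' @param k neighbor count for the fuzzy methods.
#' @return a [feature_matrix()].
#' @export
apply_imputer <- function(fm, method, k = 3L) {
  method <- match.arg(method, c("triangular", "gaussian", "mean", "median",
                                "listwise", "none"))
  switch(method,
         triangular = impute_matrix(fm, imputer_config(k, "triangular")),
         gaussian   = impute_matrix(fm, imputer_config(k, "gaussian")),
         mean       = mean_impute(fm),
         median     = median_impute(fm),
         listwise   = listwise_delete(fm),
         none       = fm)
}
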
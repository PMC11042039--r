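#' Configuration for fuzzy nearest-neighbor imputation
#'
#' @param k number of nearest complete-case neighbors used per missing cell.
#' @param membership fuzzy membership kind weighting the neighbor values:
#'   `"triangular"` (piecewise-linear over min/mean/max) or `"gaussian"`
#'   (bell curve over mean/population sd).
#' @param include_label if `TRUE` and the matrix carries a numeric-codable
#'   label, the label participates in neighbor distances; by default it is
#'   excluded.
#' @return an `imputer_config` list.
#' @export
imputer_config <- function(k = 3L,
                           membership = c("triangular", "gaussian"),
                           include_label = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be a positive integer", call. = FALSE)
  membership <- match.arg(membership)
  structure(list(k = k, membership = membership,
                 include_label = isTRUE(include_label)),
            class = "imputer_config")
}

#' Euclidean distance between two complete rows over a column set
#'
#' Square root of the sum of squared differences over the given columns.
#' Both rows must be observed at every compared column; the caller is
#' responsible for restricting to columns where that holds.
#'
#' @param target_row,candidate_row numeric vectors (full rows).
#' @param columns integer indices of the columns entering the distance.
#' @return non-negative distance, symmetric in the two rows.
#' @examples
#' complete_case_distance(c(23, 100, 0.9, 3, 0),
#'                        c(0, 100, 0.2, 2, 0), 1:5)  # 23.03237
#' @export
complete_case_distance <- function(target_row, candidate_row, columns) {
  if (length(columns) < 1L) stop("`columns` must be non-empty", call. = FALSE)
  a <- target_row[columns]
  b <- candidate_row[columns]
  if (anyNA(a) || anyNA(b)) {
    stop("rows must be observed at every compared column", call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

# Distance columns for imputing cell (row, target_col): every feature column
# except the target, restricted to columns observed in the target row, with
# the label never entering (it lives outside fm$x; include_label appends it).
distance_columns <- function(fm, row, target_col) {
  cols <- setdiff(seq_len(ncol(fm$x)), target_col)
  cols[!is.na(fm$x[row, cols])]
}

#' Select the k nearest complete-case neighbors of a missing cell
#'
#' Candidate rows are those observed at the target column and at every
#' distance column (all feature columns other than the target, restricted
#' to the columns where the target row itself is observed). Candidates are
#' ranked by Euclidean distance to the target row; ties are broken in
#' favour of the lower row index, and at most `config$k` are kept.
#'
#' @param fm a [feature_matrix()].
#' @param row,target_col position of the missing cell (the cell must be
#'   missing).
#' @param config an [imputer_config()].
#' @return a `neighbor_set` list: `values` (the candidates' target-column
#'   values), `distances` (non-decreasing), `rows` (their row indices) and
#'   `k_requested`.
#' @examples
#' select_neighbors(demo_grid(), 3, 1, imputer_config(k = 3))$values
#' @export
select_neighbors <- function(fm, row, target_col, config = imputer_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!is.na(fm$x[row, target_col])) {
    stop("cell (", row, ", ", target_col, ") is not missing", call. = FALSE)
  }
  dcols <- distance_columns(fm, row, target_col)
  lab <- NULL
  if (config$include_label && !is.null(fm$label)) {
    lab <- as.numeric(fm$label)
  }
  cand <- which(!is.na(fm$x[, target_col]))
  cand <- setdiff(cand, row)
  if (length(dcols) > 0L) {
    ok <- rowSums(is.na(fm$x[cand, dcols, drop = FALSE])) == 0L
    cand <- cand[ok]
  }
  if (length(cand) == 0L || length(dcols) == 0L) {
    stop("no eligible complete-case neighbors for cell (", row, ", ",
         target_col, ")", call. = FALSE)
  }
  target <- fm$x[row, dcols]
  diffs <- sweep(fm$x[cand, dcols, drop = FALSE], 2, target)
  d2 <- rowSums(diffs^2)
  if (!is.null(lab)) d2 <- d2 + (lab[cand] - lab[row])^2
  d <- sqrt(d2)
  ord <- order(d, cand)
  keep <- ord[seq_len(min(config$k, length(ord)))]
  structure(list(values = unname(fm$x[cand[keep], target_col]),
                 distances = unname(d[keep]),
                 rows = cand[keep],
                 k_requested = config$k),
            class = "neighbor_set")
}

# Fuzzy weighted average of a neighbor value set, with the degenerate
# fallbacks: identical values -> that value; all-zero triangular weights or
# zero Gaussian spread -> plain mean of the neighbor values.
fuzzy_estimate <- function(values, membership) {
  if (length(unique(values)) == 1L) {
    return(list(value = values[1L], fallback = "identical_values"))
  }
  if (membership == "triangular") {
    w <- triangular_membership(values, triangular_params(values))
    if (sum(w) <= 0) {
      return(list(value = mean(values), fallback = "all_zero_weights"))
    }
  } else {
    gp <- gaussian_params(values)
    if (gp$sigma <= 0) {
      return(list(value = mean(values), fallback = "zero_sigma"))
    }
    w <- gaussian_membership(values, gp)
  }
  list(value = weighted_average(values, w), fallback = NA_character_)
}

#' Impute one missing cell by fuzzy-weighted nearest neighbors
#'
#' Composes [select_neighbors()], the membership fit
#' ([triangular_params()] or [gaussian_params()]), the membership weights
#' and [weighted_average()]. Degenerate situations resolve through a
#' fallback chain instead of erroring: identical neighbor values are
#' imputed directly; an all-zero triangular weight set or a zero Gaussian
#' spread falls back to the arithmetic mean of the neighbor values; a cell
#' with no eligible neighbors falls back to the column mean of observed
#' values.
#'
#' @inheritParams select_neighbors
#' @param col column index of the missing cell.
#' @return the imputed value, with attribute `"fallback"` naming the
#'   fallback used (or `NA` when the ordinary weighted average applied).
#' @examples
#' impute_cell(demo_grid(), 3, 1, imputer_config(membership = "gaussian"))
#' @export
impute_cell <- function(fm, row, col, config = imputer_config()) {
  ns <- tryCatch(select_neighbors(fm, row, col, config),
                 error = function(e) NULL)
  if (is.null(ns)) {
    obs <- fm$x[, col]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0L) {
      stop("column ", col, " has no observed values to fall back on",
           call. = FALSE)
    }
    return(structure(mean(obs), fallback = "column_mean"))
  }
  est <- fuzzy_estimate(ns$values, config$membership)
  structure(est$value, fallback = est$fallback)
}

#' Impute every missing cell of a feature matrix
#'
#' Each originally missing cell is imputed with [impute_cell()] computed
#' against the ORIGINAL matrix, so freshly imputed values never feed into
#' later neighbor searches and the result is independent of processing
#' order. Observed cells are returned unchanged.
#'
#' @param fm a [feature_matrix()]; any column that is entirely missing is
#'   an error.
#' @param config an [imputer_config()].
#' @return a complete [feature_matrix()] with attribute `"fallbacks"`, a
#'   data frame logging every cell that resolved through a fallback.
#' @examples
#' out <- impute_matrix(demo_grid(), imputer_config(k = 3))
#' out$x[3, "A"]  # 2
#' @export
impute_matrix <- function(fm, config = imputer_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  all_missing <- colSums(!is.na(fm$x)) == 0L
  if (any(all_missing)) {
    stop("column(s) entirely missing, cannot impute: ",
         paste(colnames(fm$x)[all_missing], collapse = ", "), call. = FALSE)
  }
  idx <- which(is.na(fm$x), arr.ind = TRUE)
  out <- fm
  fb <- list()
  for (m in seq_len(nrow(idx))) {
    i <- idx[m, 1L]; j <- idx[m, 2L]
    v <- impute_cell(fm, i, j, config)
    out$x[i, j] <- as.numeric(v)
    if (!is.na(attr(v, "fallback"))) {
      fb[[length(fb) + 1L]] <- data.frame(row = i, col = j,
                                          fallback = attr(v, "fallback"))
    }
  }
  attr(out, "fallbacks") <- if (length(fb)) do.call(rbind, fb) else
    data.frame(row = integer(), col = integer(), fallback = character())
  out
}
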
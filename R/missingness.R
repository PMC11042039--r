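#' Inject missing-completely-at-random cells into a complete matrix
#'
#' Blanks exactly `round(proportion * n_cells)` feature cells, chosen
#' uniformly without replacement under the constraint that no observation
#' loses all of its feature values (the cells are visited in a seeded
#' random order and any cell whose removal would empty a row is skipped).
#' The label is never touched.
#'
#' @param fm a complete [feature_matrix()] (no missing feature cells).
#' @param proportion fraction of feature cells to blank, in \[0, 1).
#' @param seed integer seed; identical seeds give identical masks.
#' @return list with `matrix` (the injected [feature_matrix()]) and `mask`
#'   (logical matrix, `TRUE` at injected cells).
#' @examples
#' fm <- generate_synthetic(synthetic_spec(n_rows = 20, n_features = 5))
#' inj <- inject_mcar(fm, 0.10, seed = 1)
#' sum(inj$mask)  # 10
#' @export
inject_mcar <- function(fm, proportion, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (n_missing(fm) > 0L) {
    stop("input must be complete before injection", call. = FALSE)
  }
  if (proportion < 0 || proportion >= 1) {
    stop("`proportion` must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(fm$x); p <- ncol(fm$x)
  m <- round(proportion * n * p)
  mask <- matrix(FALSE, n, p, dimnames = dimnames(fm$x))
  if (m > n * (p - 1L)) {
    stop("proportion too high: some row would lose all its feature values",
         call. = FALSE)
  }
  if (m > 0L) {
    set.seed(as.integer(seed))
    ord <- sample.int(n * p)
    remaining <- rep(p, n)  # observed cells left per row
    taken <- 0L
    for (cell in ord) {
      i <- ((cell - 1L) %% n) + 1L
      if (remaining[i] <= 1L) next
      mask[cell] <- TRUE
      remaining[i] <- remaining[i] - 1L
      taken <- taken + 1L
      if (taken == m) break
    }
    if (taken < m) {
      stop("could not place the requested number of missing cells",
           call. = FALSE)
    }
  }
  out <- fm
  out$x[mask] <- NA_real_
  list(matrix = out, mask = mask)
}

#' Specification of a synthetic classification dataset
#'
#' Describes a two-class dataset of independent Gaussian features whose
#' class means are separated by `effect_size` within-class standard
#' deviations on every feature — the shape of the binary-label numeric
#' tables the package's evaluation harness targets.
#'
#' @param n_rows number of observations.
#' @param n_features number of numeric features.
#' @param class_balance probability of the positive class, strictly in
#'   (0, 1).
#' @param effect_size between-class mean shift in units of the
#'   within-class standard deviation.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_rows = 500L, n_features = 10L,
                           class_balance = 0.5, effect_size = 2,
                           seed = 1L) {
  stopifnot(n_rows >= 1L, n_features >= 1L,
            class_balance > 0, class_balance < 1)
  structure(list(n_rows = as.integer(n_rows),
                 n_features = as.integer(n_features),
                 class_balance = class_balance,
                 effect_size = effect_size,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic two-class dataset
#'
#' Draws labels Bernoulli(`class_balance`) and features independently from
#' class-conditional normal distributions: standard normal for the negative
#' class, mean `effect_size` (sd 1) for the positive class. The class
#' structure induces marginal correlation between features, which
#' neighbor-based imputation can exploit and unconditional column means
#' cannot.
#'
#' @param spec a [synthetic_spec()].
#' @return a complete [feature_matrix()] with a binary label `"class"`.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  lab <- stats::rbinom(spec$n_rows, 1L, spec$class_balance)
  x <- matrix(stats::rnorm(spec$n_rows * spec$n_features), spec$n_rows,
              spec$n_features,
              dimnames = list(NULL, paste0("f", seq_len(spec$n_features))))
  x <- x + spec$effect_size * lab
  feature_matrix(x, label = factor(lab, levels = c(0, 1)),
                 label_name = "class")
}

#' Root-mean-square error of imputation over injected cells
#'
#' Compares an imputed matrix to the pre-injection truth, restricted to
#' the injected cells; zero means every blanked value was restored
#' exactly.
#'
#' @param original the complete [feature_matrix()] before injection.
#' @param imputed the [feature_matrix()] after injection and imputation.
#' @param mask logical matrix of injected cells, as from [inject_mcar()].
#' @return the RMSE over masked cells.
#' @export
restore_truth_error <- function(original, imputed, mask) {
  stopifnot(inherits(original, "feature_matrix"),
            inherits(imputed, "feature_matrix"))
  if (!all(dim(original$x) == dim(imputed$x)) ||
      !all(dim(original$x) == dim(mask))) {
    stop("original, imputed and mask must share dimensions", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  sqrt(mean((original$x[mask] - imputed$x[mask])^2))
}
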
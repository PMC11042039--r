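#' Triangular membership parameters of a value set
#'
#' Fits the three parameters of a triangular fuzzy set to a set of neighbor
#' values: the starting point `a` is the minimum, the peak `b` is the
#' arithmetic mean, and the endpoint `c` is the maximum.
#'
#' @param values non-empty numeric vector.
#' @return list with components `a`, `b`, `c` (`a <= b <= c`).
#' @examples
#' triangular_params(c(2, 1, 7))  # a = 1, b = 10/3, c = 7
#' @export
triangular_params <- function(values) {
  if (length(values) < 1L || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  list(a = min(values), b = mean(values), c = max(values))
}

#' Triangular fuzzy membership function
#'
#' Piecewise-linear membership over the triangle `(a, b, c)`:
#' 0 for `x <= a`; `(x - a)/(b - a)` for `a < x <= b`;
#' `(c - x)/(c - b)` for `b < x < c`; 0 for `x >= c`.
#' When a branch is degenerate (`b == a` or `c == b`) that branch
#' evaluates to 0, so the function stays total and bounded in \[0, 1\].
#'
#' @param x numeric vector of evaluation points.
#' @param params parameter list from [triangular_params()].
#' @return membership degrees in \[0, 1\], same length as `x`.
#' @examples
#' p <- triangular_params(c(2, 1, 7))
#' triangular_membership(2, p)  # 0.428571...
#' @export
triangular_membership <- function(x, params) {
  a <- params$a; b <- params$b; cc <- params$c
  if (!(a <= b && b <= cc)) stop("invalid parameters: need a <= b <= c",
                                 call. = FALSE)
  out <- numeric(length(x))
  rising <- x > a & x <= b
  falling <- x > b & x < cc
  if (b > a) out[rising] <- (x[rising] - a) / (b - a)
  if (cc > b) out[falling] <- (cc - x[falling]) / (cc - b)
  pmin(pmax(out, 0), 1)
}

#' Gaussian membership parameters of a value set
#'
#' Fits the center `mu` (arithmetic mean) and width `sigma` of a Gaussian
#' fuzzy set to a set of neighbor values. `sigma` is the population
#' standard deviation (divisor equal to the number of values, not n - 1),
#' the form under which the bell curve's width matches the spread of the
#' neighbor set itself.
#'
#' @param values non-empty numeric vector.
#' @return list with components `mu` and `sigma` (`sigma >= 0`).
#' @examples
#' gaussian_params(c(2, 1, 7))  # mu = 10/3, sigma = 2.6247...
#' @export
gaussian_params <- function(values) {
  if (length(values) < 1L || anyNA(values)) {
    stop("`values` must be a non-empty numeric vector without NA",
         call. = FALSE)
  }
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  list(mu = mu, sigma = sigma)
}

#' Gaussian fuzzy membership function
#'
#' Bell-curve membership `exp(-(x - mu)^2 / (2 sigma^2))`: equals 1 at the
#' center and decays symmetrically with distance from it.
#'
#' @param x numeric vector of evaluation points.
#' @param params parameter list from [gaussian_params()]; `sigma` must be
#'   strictly positive (a zero-spread neighbor set is handled upstream by
#'   the degenerate-weight fallback of [impute_cell()]).
#' @return membership degrees in (0, 1\], same length as `x`.
#' @examples
#' p <- gaussian_params(c(2, 1, 7))
#' gaussian_membership(c(2, 1, 7), p)  # 0.8790 0.6736 0.3769
#' @export
gaussian_membership <- function(x, params) {
  if (params$sigma <= 0) {
    stop("sigma must be > 0 (zero spread: use the degenerate fallback)",
         call. = FALSE)
  }
  exp(-(x - params$mu)^2 / (2 * params$sigma^2))
}

#' Weighted average of neighbor values
#'
#' `sum(values * weights) / sum(weights)`; the result always lies within
#' the range of `values`.
#'
#' @param values numeric vector.
#' @param weights non-negative numeric vector, same length.
#' @return the weighted mean.
#' @examples
#' weighted_average(c(2, 1, 7), c(0.428571, 0, 0))  # 2
#' @export
weighted_average <- function(values, weights) {
  if (length(values) != length(weights) || length(values) < 1L) {
    stop("`values` and `weights` must have equal length >= 1", call. = FALSE)
  }
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  s <- sum(weights)
  if (s <= 0) {
    stop("all weights are zero (use the degenerate-weight fallback)",
         call. = FALSE)
  }
  sum(values * weights) / s
}
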
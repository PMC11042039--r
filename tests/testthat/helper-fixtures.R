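# Shared fixtures and independent brute-force oracles.

# Random small feature matrix with scattered missing cells; each row keeps
# at least one observed value.
random_incomplete_matrix <- function(n, p, miss_prob = 0.15, seed = 1) {
  set.seed(seed)
  x <- matrix(round(rnorm(n * p), 3), n, p)
  miss <- matrix(runif(n * p) < miss_prob, n, p)
  for (i in seq_len(n)) {
    if (all(miss[i, ])) miss[i, sample(p, 1)] <- FALSE
  }
  x[miss] <- NA_real_
  feature_matrix(x)
}

# Brute-force neighbor scan written with plain loops: recomputes every
# candidate distance from first principles and sorts, independently of the
# package's vectorized path.
brute_force_neighbors <- function(fm, row, col, k) {
  x <- fm$x
  dcols <- setdiff(seq_len(ncol(x)), col)
  dcols <- dcols[!is.na(x[row, dcols])]
  if (length(dcols) == 0) return(NULL)
  cand <- c(); dist <- c()
  for (r in seq_len(nrow(x))) {
    if (r == row || is.na(x[r, col])) next
    if (any(is.na(x[r, dcols]))) next
    s <- 0
    for (j in dcols) s <- s + (x[row, j] - x[r, j])^2
    cand <- c(cand, r); dist <- c(dist, sqrt(s))
  }
  if (length(cand) == 0) return(NULL)
  ord <- order(dist, cand)
  keep <- ord[seq_len(min(k, length(ord)))]
  list(values = unname(x[cand[keep], col]), distances = unname(dist[keep]),
       rows = cand[keep])
}
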
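# independent oracles used by the equivalence tests

# quasi-independent fit with diagonal maximisation, in closed form: after
# fixing y_ii = min(row_i, col_i), the residual row-positive and
# column-positive index sets are disjoint, so the stage-2 fit over the active
# rectangle is the outer product of the residual margins
oracle_quasi_indep <- function(rows, cols) {
  n <- length(rows)
  d <- pmin(rows, cols)
  r <- rows - d
  cc <- cols - d
  m <- matrix(0, n, n)
  if (sum(r) > 0) m <- outer(r, cc) / sum(r)
  diag(m) <- d
  m
}

# type-7 quantile from the order-statistic definition, by direct sorting
quantile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }, numeric(1))
}
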
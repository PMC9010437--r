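#' Demographically adjust stock tables for a period
#'
#' Builds the pair of adjusted stock matrices that supply the margins of the
#' birthplace-specific flow array. Home cells are first derived with
#' [native_home_stock()]. Deaths of each residence country during the period
#' are then subtracted from the start-of-period stocks, allocated
#' proportionally across birthplaces within the residence (mortality assumed
#' birthplace-neutral); sex-specific births are subtracted from the home cell
#' of the end-of-period stocks (period newborns are assumed non-migrant, so
#' removing them recovers the pre-birth population). Negative cells are clamped
#' to zero with a warning.
#'
#' @param stocks A harmonised [stock_panel()].
#' @param demo A [demographic_panel()].
#' @param period_start Start year of the five-year period.
#' @param sex `"female"`, `"male"` or `"total"`.
#' @param period_length Years per period (default 5).
#' @return An `adjusted_stock_pair`: a list with matrices `start` and `end`
#'   indexed `[birthplace, residence]`, plus `countries`, `sex`,
#'   `period_start` and a `balanced` flag.
#' @export
adjust_stocks <- function(stocks, demo, period_start, sex,
                          period_length = 5L) {
  t0 <- period_start
  t1 <- period_start + period_length
  drow <- demo[demo$period_start == period_start & demo$sex == sex, ]
  if (nrow(drow) == 0) {
    stop("no demographic rows for sex ", sex, " in period ", period_start,
         call. = FALSE)
  }
  countries <- sort(unique(drow$country))
  n <- length(countries)

  build <- function(tp) {
    m <- matrix(0, n, n, dimnames = list(countries, countries))
    sub <- stocks[stocks$year == tp & stocks$sex == sex &
                    stocks$birthplace != stocks$residence &
                    stocks$birthplace %in% countries &
                    stocks$residence %in% countries, ]
    m[cbind(match(sub$birthplace, countries),
            match(sub$residence, countries))] <- sub$stock
    home <- native_home_stock(stocks[stocks$sex == sex, ],
                              demo[demo$sex == sex, ], tp)
    home <- home[home$country %in% countries, ]
    diag(m)[match(home$country, countries)] <- home$home_stock
    m
  }
  m0 <- build(t0)
  m1 <- build(t1)

  # deaths: proportional removal across birthplace within residence
  deaths <- drow$deaths[match(countries, drow$country)]
  for (j in seq_len(n)) {
    tot <- sum(m0[, j])
    if (deaths[j] > tot) {
      warning(sprintf(
        "deaths exceed resident stocks in %s, period %d: clamping to 0",
        countries[j], period_start), call. = FALSE)
      m0[, j] <- 0
    } else if (tot > 0) {
      m0[, j] <- m0[, j] * (1 - deaths[j] / tot)
    }
  }

  # births: removed from the end-of-period home cell
  births <- split_births_by_sex(drow$births_total, drow$srb)
  b <- switch(sex, female = births$female, male = births$male,
              drow$births_total)
  b <- b[match(countries, drow$country)]
  newdiag <- diag(m1) - b
  neg <- newdiag < 0
  if (any(neg)) {
    warning(sprintf(
      "births exceed home stocks in %s, period %d: clamping to 0",
      paste(countries[neg], collapse = ", "), period_start), call. = FALSE)
    newdiag[neg] <- 0
  }
  diag(m1) <- newdiag

  structure(list(start = m0, end = m1, countries = countries, sex = sex,
                 period_start = as.integer(period_start),
                 balanced = "none", out_origin = NULL, out_dest = NULL),
            class = "adjusted_stock_pair")
}

#' @export
print.adjusted_stock_pair <- function(x, ...) {
  cat(sprintf("<adjusted_stock_pair> %s, period %d, %d countries, %s system\n",
              x$sex, x$period_start, length(x$countries),
              if (x$balanced == "none") "unbalanced" else x$balanced))
  invisible(x)
}

#' Balance an adjusted pair with an open demographic system
#'
#' Per birthplace, any discrepancy between the start (origin) and end
#' (destination) totals is absorbed by an additional outside origin or
#' destination ("OUT") covering countries not in the bilateral table: the OUT
#' origin margin is `max(0, end_total - start_total)` and the OUT destination
#' margin is `max(0, start_total - end_total)`, so the extended totals balance
#' exactly. The OUT x OUT cell is structurally zero.
#'
#' @param pair An `adjusted_stock_pair` from [adjust_stocks()].
#' @return The pair with `out_origin`/`out_dest` vectors (one entry per
#'   birthplace) and `balanced = "open"`.
#' @export
balance_open <- function(pair) {
  stopifnot(inherits(pair, "adjusted_stock_pair"))
  R <- rowSums(pair$start)
  C <- rowSums(pair$end)
  pair$out_origin <- pmax(0, C - R)
  pair$out_dest <- pmax(0, R - C)
  pair$balanced <- "open"
  pair
}

#' Balance an adjusted pair with a closed demographic system
#'
#' Per birthplace, the start and end stock vectors are scaled to the mid-point
#' of their totals: with totals `R` and `C`, both are rescaled to
#' `T = (R + C) / 2` (start by `T/R`, end by `T/C`). This is the scaling that
#' constrains estimated bilateral flows to sum to net migration per country.
#'
#' @param pair An `adjusted_stock_pair` from [adjust_stocks()].
#' @return The pair with rescaled matrices and `balanced = "closed"`.
#' @export
balance_closed <- function(pair) {
  stopifnot(inherits(pair, "adjusted_stock_pair"))
  R <- rowSums(pair$start)
  C <- rowSums(pair$end)
  one_zero <- xor(R == 0, C == 0)
  if (any(one_zero)) {
    stop("cannot scale birthplace ", pair$countries[which(one_zero)[1]],
         ": exactly one of the start/end totals is zero", call. = FALSE)
  }
  target <- (R + C) / 2
  start_f <- ifelse(R > 0, target / R, 1)
  end_f <- ifelse(C > 0, target / C, 1)
  pair$start <- pair$start * start_f # rows recycle down columns: scale per k
  pair$end <- pair$end * end_f
  pair$balanced <- "closed"
  pair
}

#' Iterative proportional fitting
#'
#' Alternating row/column scaling of a non-negative seed matrix to match target
#' margins. Structural zeros are encoded as zero seed cells and remain zero.
#' Convergence is declared when the largest absolute deviation of row and
#' column sums from their targets falls below `tol` (persons).
#'
#' @param seed Non-negative seed matrix.
#' @param row_targets,col_targets Target margins; their sums must agree.
#' @param tol Absolute convergence tolerance (default `1e-6`).
#' @param max_iter Maximum sweeps (default 1000).
#' @return The fitted matrix.
#' @export
ipf_fit <- function(seed, row_targets, col_targets, tol = 1e-6,
                    max_iter = 1000L) {
  stopifnot(nrow(seed) == length(row_targets),
            ncol(seed) == length(col_targets))
  if (abs(sum(row_targets) - sum(col_targets)) >
      tol * max(1, sum(row_targets))) {
    stop("row and column targets have different totals", call. = FALSE)
  }
  m <- seed
  if (sum(row_targets) == 0) return(m * 0)
  for (iter in seq_len(max_iter)) {
    rs <- rowSums(m)
    m <- m * ifelse(rs > 0, row_targets / rs, 0)
    cs <- colSums(m)
    m <- sweep(m, 2, ifelse(cs > 0, col_targets / cs, 0), "*")
    dev <- max(abs(rowSums(m) - row_targets), abs(colSums(m) - col_targets))
    if (dev < tol) return(m)
  }
  stop(sprintf(
    "IPF did not converge in %d sweeps (worst margin deviation %.3g)",
    max_iter, dev), call. = FALSE)
}

# margins of one birthplace slice, with OUT entries appended for open systems
slice_margins <- function(pair, k) {
  rows <- pair$start[k, ]
  cols <- pair$end[k, ]
  if (pair$balanced == "open") {
    rows <- c(rows, OUT = unname(pair$out_origin[k]))
    cols <- c(cols, OUT = unname(pair$out_dest[k]))
  }
  list(rows = rows, cols = cols)
}

#' Minimisation (diagonal-maximising quasi-independent) imputation
#'
#' Imputes the birthplace-specific flow array in two stages. Stage 1 sets each
#' diagonal stayer cell `y_iik` to its maximum feasible value,
#' `min(row_i, col_i)`, which minimises total migration given the margins.
#' Stage 2 fits the off-diagonal cells by iterative proportional fitting of a
#' quasi-independent log-linear model: a flat seed of 1 in permitted cells
#' (diagonal and the OUT x OUT cell held structurally zero) scaled to the
#' residual row/column margins left after removing the fixed diagonal.
#'
#' @param pair A balanced `adjusted_stock_pair` ([balance_open()] or
#'   [balance_closed()]).
#' @param tol,max_iter IPF controls passed to [ipf_fit()].
#' @return A `birthplace_flow_array`: array `[origin, destination, birthplace]`
#'   with an extra OUT origin/destination index for open systems.
#' @export
impute_min <- function(pair, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(pair, "adjusted_stock_pair"))
  if (pair$balanced == "none") {
    stop("pair must be balanced (balance_open or balance_closed) first",
         call. = FALSE)
  }
  n <- length(pair$countries)
  open <- pair$balanced == "open"
  dim_n <- n + as.integer(open)
  labels <- if (open) c(pair$countries, "OUT") else pair$countries
  arr <- array(0, dim = c(dim_n, dim_n, n),
               dimnames = list(labels, labels, pair$countries))
  for (k in seq_len(n)) {
    mg <- slice_margins(pair, k)
    d <- pmin(mg$rows[seq_len(n)], mg$cols[seq_len(n)])
    r <- mg$rows
    r[seq_len(n)] <- r[seq_len(n)] - d
    cc <- mg$cols
    cc[seq_len(n)] <- cc[seq_len(n)] - d
    seed <- matrix(1, dim_n, dim_n)
    diag(seed)[seq_len(n)] <- 0
    if (open) seed[dim_n, dim_n] <- 0
    slice <- ipf_fit(seed, r, cc, tol = tol, max_iter = max_iter)
    diag(slice)[seq_len(n)] <- d
    arr[, , k] <- slice
  }
  new_flow_array(arr, pair, imputation = "min")
}

#' Independent (unrestricted log-linear) imputation
#'
#' Fits the birthplace-specific flow array under full independence of origin
#' and destination given the margins: `y_ijk = row_i * col_j / sum(rows)` per
#' birthplace, diagonal included. This is the closed form the iterative
#' proportional fit of the independent log-linear model converges to. Defined
#' for closed-system pairs.
#'
#' @param pair A closed balanced `adjusted_stock_pair`.
#' @return A `birthplace_flow_array`.
#' @export
impute_indep <- function(pair) {
  stopifnot(inherits(pair, "adjusted_stock_pair"))
  if (pair$balanced != "closed") {
    stop("independent imputation is defined for closed-system pairs",
         call. = FALSE)
  }
  n <- length(pair$countries)
  arr <- array(0, dim = c(n, n, n),
               dimnames = list(pair$countries, pair$countries,
                               pair$countries))
  for (k in seq_len(n)) {
    rows <- pair$start[k, ]
    cols <- pair$end[k, ]
    tot <- sum(rows)
    if (tot > 0) arr[, , k] <- outer(rows, cols) / tot
  }
  new_flow_array(arr, pair, imputation = "indep")
}

new_flow_array <- function(arr, pair, imputation) {
  structure(arr, countries = pair$countries, sex = pair$sex,
            period_start = pair$period_start,
            system = pair$balanced, imputation = imputation,
            class = c("birthplace_flow_array", "array"))
}

#' @export
print.birthplace_flow_array <- function(x, ...) {
  cat(sprintf(
    "<birthplace_flow_array> %s, period %d, %d countries, %s system, %s imputation\n",
    attr(x, "sex"), attr(x, "period_start"), length(attr(x, "countries")),
    attr(x, "system"), attr(x, "imputation")))
  invisible(x)
}

#' Pseudo-Bayesian combination of two imputations
#'
#' Cell-wise weighted combination of the minimisation and independent
#' imputations, `w1 * arr_min + (1 - w1) * arr_indep`, with the default weight
#' of 0.87 in favour of the minimisation imputation.
#'
#' @param arr_min,arr_indep Same-shape `birthplace_flow_array`s from
#'   [impute_min()] and [impute_indep()] on the same closed pair.
#' @param w1 Weight on the minimisation imputation, in `[0, 1]` (default 0.87).
#' @return A `birthplace_flow_array`.
#' @export
pseudo_bayes <- function(arr_min, arr_indep, w1 = 0.87) {
  if (!isTRUE(all.equal(dim(arr_min), dim(arr_indep)))) {
    stop("imputation arrays have different shapes", call. = FALSE)
  }
  if (w1 < 0 || w1 > 1) stop("w1 must lie in [0, 1]", call. = FALSE)
  out <- unclass(arr_min) * w1 + unclass(arr_indep) * (1 - w1)
  attributes(out) <- attributes(arr_min)
  attr(out, "imputation") <- "pseudo_bayes"
  out
}

#' Bilateral flows from a birthplace-specific flow array
#'
#' Sums the array over the birthplace dimension and returns the off-diagonal
#' origin-destination cells. OUT rows and columns of open systems are excluded
#' from the bilateral output.
#'
#' @param arr A `birthplace_flow_array`.
#' @return A tibble `sex`, `orig`, `dest`, `period_start`, `flow`.
#' @export
flows_from_array <- function(arr) {
  countries <- attr(arr, "countries")
  n <- length(countries)
  tot <- apply(unclass(arr)[seq_len(n), seq_len(n), , drop = FALSE], c(1, 2),
               sum)
  idx <- which(row(tot) != col(tot), arr.ind = TRUE)
  tibble::tibble(sex = attr(arr, "sex"), orig = countries[idx[, 1]],
                 dest = countries[idx[, 2]],
                 period_start = attr(arr, "period_start"),
                 flow = tot[idx])
}

#' Decompose bilateral flows by move type
#'
#' Splits each corridor's flow by the migrant's birthplace: outward migrants
#' move away from their country of birth (`k = orig`), return migrants move to
#' it (`k = dest`), transit migrants move between countries neither of which is
#' their birthplace. The three types partition each corridor's flow exactly.
#'
#' @param arr A `birthplace_flow_array`.
#' @return A tibble `sex`, `move_type`, `orig`, `dest`, `period_start`, `flow`.
#' @export
move_type_decompose <- function(arr) {
  countries <- attr(arr, "countries")
  n <- length(countries)
  a <- unclass(arr)[seq_len(n), seq_len(n), , drop = FALSE]
  tot <- apply(a, c(1, 2), sum)
  idx <- which(row(tot) != col(tot), arr.ind = TRUE)
  outward <- a[cbind(idx[, 1], idx[, 2], idx[, 1])]
  return_ <- a[cbind(idx[, 1], idx[, 2], idx[, 2])]
  transit <- tot[idx] - outward - return_
  base <- tibble::tibble(sex = attr(arr, "sex"),
                         orig = countries[idx[, 1]],
                         dest = countries[idx[, 2]],
                         period_start = attr(arr, "period_start"))
  dplyr::bind_rows(
    dplyr::mutate(base, move_type = "outward", flow = outward),
    dplyr::mutate(base, move_type = "return", flow = return_),
    dplyr::mutate(base, move_type = "transit", flow = pmax(transit, 0)))[
      , c("sex", "move_type", "orig", "dest", "period_start", "flow")]
}
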
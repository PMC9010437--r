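#' Sum a stock panel over sexes
#'
#' Collapses female and male records into `sex = "total"` records, used to
#' probe discrepancies between total-stock-based estimates and the sum of
#' sex-specific estimates.
#'
#' @param stocks A [stock_panel()].
#' @return A [stock_panel()] with a single `"total"` sex.
#' @export
sum_sexes <- function(stocks) {
  out <- dplyr::summarise(
    dplyr::group_by(stocks, .data$birthplace, .data$residence, .data$year),
    stock = sum(.data$stock), .groups = "drop")
  out$sex <- "total"
  stock_panel(out[, c("sex", "birthplace", "residence", "year", "stock")])
}

#' Five-year equivalents of annual reported flows
#'
#' Reported migration statistics are annual while the estimates cover five-year
#' periods. The equivalent five-year reported flow for a corridor is the mean
#' of the annual flows available within the period's five calendar years
#' (`t .. t+4`), multiplied by five. Corridors with no annual data in a period
#' are omitted, not zero-filled.
#'
#' @param reported A tibble of annual reported flows with columns `orig`,
#'   `dest`, `year`, `flow` and optionally `sex`.
#' @param period_starts Integer vector of period start years.
#' @param period_length Years per period (default 5).
#' @return A tibble `sex` (if present), `orig`, `dest`, `period_start`,
#'   `flow_5yr`, `n_years`.
#' @export
five_year_equivalent <- function(reported, period_starts, period_length = 5L) {
  if (any(reported$flow < 0)) {
    stop("reported flows must be non-negative", call. = FALSE)
  }
  has_sex <- "sex" %in% names(reported)
  if (!has_sex) reported$sex <- "total"
  out <- list()
  for (p in period_starts) {
    in_p <- reported[reported$year >= p & reported$year < p + period_length, ]
    if (nrow(in_p) == 0) next
    eq <- dplyr::summarise(
      dplyr::group_by(in_p, .data$sex, .data$orig, .data$dest),
      flow_5yr = mean(.data$flow) * 5, n_years = dplyr::n(),
      .groups = "drop")
    eq$period_start <- as.integer(p)
    out[[as.character(p)]] <- eq
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(sex = character(), orig = character(),
                          dest = character(), flow_5yr = numeric(),
                          n_years = integer(), period_start = integer())
  }
  res[, c("sex", "orig", "dest", "period_start", "flow_5yr", "n_years")]
}

#' Paired migration measures for validation
#'
#' Builds the six validation measures as paired (estimated, reported) vectors
#' over matched keys: bilateral flow counts; their natural logarithms (pairs
#' with a zero on either side dropped, or shifted by one under
#' `log_zero = "add1"`); the proportion of flows into the destination and out
#' of the origin; immigration and emigration rates (country totals divided by
#' the start-of-period population of the destination or origin); and net
#' migration counts per country.
#'
#' @param est A tibble `sex`, `orig`, `dest`, `period_start`, `flow` of
#'   estimated flows (one method).
#' @param ref Output of [five_year_equivalent()] (columns `flow_5yr`).
#' @param demo A [demographic_panel()] supplying start-of-period populations.
#' @param log_zero `"drop"` (default) or `"add1"` for the log measure.
#' @return A named list of tibbles, one per measure, each with columns
#'   identifying the key plus `est` and `ref`.
#' @export
compute_measures <- function(est, ref, demo, log_zero = c("drop", "add1")) {
  log_zero <- match.arg(log_zero)
  keys <- c("sex", "orig", "dest", "period_start")
  ref2 <- ref
  names(ref2)[names(ref2) == "flow_5yr"] <- "ref"
  est2 <- est
  names(est2)[names(est2) == "flow"] <- "est"
  matched <- dplyr::inner_join(est2[, c(keys, "est")],
                               ref2[, c(keys, "ref")], by = keys)

  count <- matched
  if (log_zero == "drop") {
    lc <- matched[matched$est > 0 & matched$ref > 0, ]
    lc$est <- log(lc$est)
    lc$ref <- log(lc$ref)
  } else {
    lc <- matched
    lc$est <- log(lc$est + 1)
    lc$ref <- log(lc$ref + 1)
  }

  prop_of <- function(d, by_col) {
    g <- dplyr::group_by(d, .data$sex, .data$period_start, .data[[by_col]])
    d2 <- dplyr::mutate(g, est_tot = sum(.data$est), ref_tot = sum(.data$ref))
    d2 <- dplyr::ungroup(d2)
    keep <- d2$est_tot > 0 & d2$ref_tot > 0
    d2 <- d2[keep, ]
    d2$est <- d2$est / d2$est_tot
    d2$ref <- d2$ref / d2$ref_tot
    d2[, c(keys, "est", "ref")]
  }
  proportion_in <- prop_of(matched, "dest")
  proportion_out <- prop_of(matched, "orig")

  pops <- unique(demo[, c("country", "period_start", "sex", "pop_start")])
  country_totals <- function(by_col) {
    g <- dplyr::group_by(matched, .data$sex, .data$period_start,
                         country = .data[[by_col]])
    tot <- dplyr::summarise(g, est = sum(.data$est), ref = sum(.data$ref),
                            .groups = "drop")
    tot
  }
  rate_of <- function(by_col) {
    tot <- country_totals(by_col)
    tot <- dplyr::left_join(tot, pops,
                            by = c("country", "period_start", "sex"))
    zero_pop <- is.na(tot$pop_start) | tot$pop_start == 0
    if (any(zero_pop)) {
      warning("dropping ", sum(zero_pop),
              " country-period(s) with missing or zero population",
              call. = FALSE)
      tot <- tot[!zero_pop, ]
    }
    tot$est <- tot$est / tot$pop_start
    tot$ref <- tot$ref / tot$pop_start
    tot[, c("sex", "country", "period_start", "est", "ref")]
  }
  imm_rate <- rate_of("dest")
  emi_rate <- rate_of("orig")

  inflow <- country_totals("dest")
  outflow <- country_totals("orig")
  net <- dplyr::full_join(
    inflow, outflow, by = c("sex", "period_start", "country"),
    suffix = c("_in", "_out"))
  for (col in c("est_in", "ref_in", "est_out", "ref_out")) {
    net[[col]][is.na(net[[col]])] <- 0
  }
  net_count <- tibble::tibble(sex = net$sex, country = net$country,
                              period_start = net$period_start,
                              est = net$est_in - net$est_out,
                              ref = net$ref_in - net$ref_out)

  list(count = count[, c(keys, "est", "ref")], log_count = lc[, c(keys, "est", "ref")],
       proportion_in = proportion_in, proportion_out = proportion_out,
       imm_rate = imm_rate, emi_rate = emi_rate, net_count = net_count)
}

#' Pearson correlation of a paired measure
#'
#' Product-moment correlation of the `est` and `ref` columns. Returns `NA`
#' with a warning when fewer than two pairs are available or either vector has
#' zero variance.
#'
#' @param measure A tibble with `est` and `ref` columns.
#' @return A length-one numeric in `[-1, 1]`, or `NA`.
#' @export
pearson_cor <- function(measure) {
  x <- measure$est
  y <- measure$ref
  if (length(x) < 2 || stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined: fewer than 2 pairs or zero variance",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y, method = "pearson")
}

#' Tidy correlation table across measures
#'
#' Applies [compute_measures()] and [pearson_cor()] per sex, returning a tidy
#' table suitable for heat-map style summaries.
#'
#' @param est Estimated flows (`sex`, `orig`, `dest`, `period_start`, `flow`).
#' @param ref Output of [five_year_equivalent()].
#' @param demo A [demographic_panel()].
#' @param method Label recorded in the output.
#' @param source Label for the reported-data source.
#' @param log_zero Passed to [compute_measures()].
#' @return A tibble `source`, `sex`, `method`, `measure`, `r`, `n_pairs`.
#' @export
correlate_measures <- function(est, ref, demo, method = "method",
                               source = "reported", log_zero = "drop") {
  out <- list()
  for (s in unique(est$sex)) {
    mv <- compute_measures(est[est$sex == s, ], ref[ref$sex == s, ],
                           demo, log_zero = log_zero)
    for (m in names(mv)) {
      r <- suppressWarnings(pearson_cor(mv[[m]]))
      out[[paste(s, m)]] <- tibble::tibble(
        source = source, sex = s, method = method, measure = m,
        r = r, n_pairs = nrow(mv[[m]]))
    }
  }
  dplyr::bind_rows(out)
}

#' Discrepancy summary between total-based and sex-summed estimates
#'
#' Distribution statistics of the corridor-level discrepancy
#' `total-based - (female + male)` per method: mean, median, standard
#' deviation, interquartile range (p75 - p25), interdecile range (p90 - p10),
#' 99th interpercentile range (p99.5 - p0.5), minimum and maximum. Percentiles
#' use linear interpolation between order statistics.
#'
#' @param total_based Wide flow table (`sex = "total"`) with one column per
#'   method plus `orig`, `dest`, `period_start`.
#' @param sex_summed Same layout, holding female + male sums per corridor.
#' @param methods Method columns to summarise (default: all shared columns
#'   among the six method keys).
#' @return A tibble `method`, `mean`, `median`, `sd`, `iqr`, `idr`, `ipr99`,
#'   `min`, `max`.
#' @export
discrepancy_summary <- function(total_based, sex_summed, methods = NULL) {
  keys <- c("orig", "dest", "period_start")
  all_methods <- c("sd_drop_neg", "sd_rev_neg", "mig_rate",
                   "da_min_open", "da_min_closed", "da_pb_closed")
  if (is.null(methods)) {
    methods <- intersect(all_methods,
                         intersect(names(total_based), names(sex_summed)))
  }
  if (length(methods) == 0) stop("no method columns to compare", call. = FALSE)
  a <- total_based[do.call(order, total_based[keys]), ]
  b <- sex_summed[do.call(order, sex_summed[keys]), ]
  if (nrow(a) != nrow(b) ||
      !all(a$orig == b$orig & a$dest == b$dest &
             a$period_start == b$period_start)) {
    stop("corridor sets of the two estimate tables do not match",
         call. = FALSE)
  }
  rows <- lapply(methods, function(m) {
    d <- a[[m]] - b[[m]]
    q <- stats::quantile(d, c(0.005, 0.10, 0.25, 0.75, 0.90, 0.995),
                         names = FALSE, type = 7)
    tibble::tibble(method = m, mean = mean(d), median = stats::median(d),
                   sd = stats::sd(d), iqr = q[4] - q[3], idr = q[5] - q[2],
                   ipr99 = q[6] - q[1], min = min(d), max = max(d))
  })
  dplyr::bind_rows(rows)
}
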
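method_keys <- c("sd_drop_neg", "sd_rev_neg", "mig_rate",
                 "da_min_open", "da_min_closed", "da_pb_closed")
accounting_keys <- c("da_min_open", "da_min_closed", "da_pb_closed")

#' Estimate bilateral flows with all requested methods
#'
#' Runs the full pipeline: harmonisation, net-migration derivation, and the
#' six estimators per sex and period, returning the two standard output tables.
#' The flow table holds one row per (sex, origin, destination, period) cell of
#' the full origin x destination grid (`layout = "grid"`, the published
#' layout, with zero flows on the `orig == dest` diagonal) or corridors only
#' (`layout = "corridor"`). The move-type table covers the three demographic
#' accounting methods, with one row per (sex, move type, origin, destination,
#' period).
#'
#' @param stocks A [stock_panel()].
#' @param demo A [demographic_panel()].
#' @param methods Subset of
#'   `c("sd_drop_neg","sd_rev_neg","mig_rate","da_min_open","da_min_closed","da_pb_closed")`.
#' @param w1 Pseudo-Bayesian weight on the minimisation imputation
#'   (default 0.87).
#' @param tol,max_iter IPF controls.
#' @param halve_total Passed to [global_flow_total()].
#' @param layout `"grid"` (default) or `"corridor"`.
#' @param period_length Years per period (default 5).
#' @return A list with tibbles `flows` and `move_types` (the latter `NULL`
#'   when no accounting method is requested), plus the harmonised `countries`
#'   panel.
#' @export
estimate_all <- function(stocks, demo, methods = method_keys, w1 = 0.87,
                         tol = 1e-6, max_iter = 1000L, halve_total = FALSE,
                         layout = c("grid", "corridor"), period_length = 5L) {
  layout <- match.arg(layout)
  bad <- setdiff(methods, method_keys)
  if (length(bad) > 0) {
    stop("unknown method keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  h <- harmonize(stocks, demo, period_length = period_length)
  demo_d <- derive_net_migration(h$demo)
  periods <- sort(unique(h$countries$period_start))
  sexes <- sort(unique(h$stocks$sex))
  need_acct <- length(intersect(methods, accounting_keys)) > 0
  need_rates <- "mig_rate" %in% methods
  totals <- if (need_rates) global_flow_total(demo_d, halve_total) else NULL

  flow_parts <- list()
  mt_parts <- list()
  for (p in periods) {
    per_method <- list()
    if (any(c("sd_drop_neg", "sd_rev_neg") %in% methods)) {
      diffs <- difference_stocks(h$stocks, p, period_length)
      if ("sd_drop_neg" %in% methods) {
        per_method$sd_drop_neg <- drop_negative(diffs)
      }
      if ("sd_rev_neg" %in% methods) {
        per_method$sd_rev_neg <- reverse_negative(diffs)
      }
    }
    if (need_rates) {
      per_method$mig_rate <- rate_allocate(h$stocks, totals, p)
    }
    if (need_acct) {
      for (s in sexes) {
        tryCatch({
          pair <- adjust_stocks(h$stocks, demo_d, p, s, period_length)
          arrays <- list()
          if ("da_min_open" %in% methods) {
            arrays$da_min_open <- impute_min(balance_open(pair), tol, max_iter)
          }
          if (any(c("da_min_closed", "da_pb_closed") %in% methods)) {
            closed <- balance_closed(pair)
            arr_min <- impute_min(closed, tol, max_iter)
            if ("da_min_closed" %in% methods) {
              arrays$da_min_closed <- arr_min
            }
            if ("da_pb_closed" %in% methods) {
              arrays$da_pb_closed <-
                pseudo_bayes(arr_min, impute_indep(closed), w1)
            }
          }
          for (m in names(arrays)) {
            fl <- flows_from_array(arrays[[m]])
            names(fl)[names(fl) == "flow"] <- m
            per_method[[m]] <- dplyr::bind_rows(per_method[[m]], fl)
            mt <- move_type_decompose(arrays[[m]])
            names(mt)[names(mt) == "flow"] <- m
            mt_parts[[m]] <- dplyr::bind_rows(mt_parts[[m]], mt)
          }
        }, error = function(e) {
          stop(sprintf("accounting estimation failed for %s, period %d: %s",
                       s, p, conditionMessage(e)), call. = FALSE)
        })
      }
    }
    keys <- c("sex", "orig", "dest", "period_start")
    merged <- Reduce(function(a, b) dplyr::full_join(a, b, by = keys),
                     per_method)
    flow_parts[[as.character(p)]] <- merged
  }
  flows <- dplyr::bind_rows(flow_parts)
  flows <- expand_layout(flows, h$countries, sexes, layout,
                         intersect(method_keys, methods))

  move_types <- NULL
  if (need_acct) {
    keys_mt <- c("sex", "move_type", "orig", "dest", "period_start")
    move_types <- Reduce(function(a, b) dplyr::full_join(a, b, by = keys_mt),
                         mt_parts)
    move_types <- expand_layout(move_types, h$countries, sexes, layout,
                                intersect(accounting_keys, methods),
                                move_types = TRUE)
  }
  list(flows = flows, move_types = move_types, countries = h$countries)
}

# complete an estimate table over the full key grid (or corridors only)
expand_layout <- function(est, countries, sexes, layout, methods,
                          move_types = FALSE) {
  grids <- lapply(split(countries$country, countries$period_start),
                  function(cc) {
                    g <- tidyr::expand_grid(sex = sexes, orig = cc, dest = cc)
                    if (layout == "corridor") g <- g[g$orig != g$dest, ]
                    g
                  })
  grid <- dplyr::bind_rows(grids, .id = "period_start")
  grid$period_start <- as.integer(grid$period_start)
  keys <- c("sex", "orig", "dest", "period_start")
  if (move_types) {
    grid <- tidyr::expand_grid(grid,
                               move_type = c("outward", "return", "transit"))
    keys <- c(keys, "move_type")
  }
  out <- dplyr::left_join(grid, est, by = keys)
  for (m in methods) out[[m]][is.na(out[[m]])] <- 0
  cols <- if (move_types) {
    c("sex", "move_type", "orig", "dest", "period_start", methods)
  } else {
    c("sex", "orig", "dest", "period_start", methods)
  }
  out <- out[, cols]
  out[do.call(order, out[setdiff(cols, methods)]), ]
}

#' Summary statistics of estimated flows
#'
#' Per sex, period and method: the total flow (persons per five-year period),
#' the crude migration rate (migrants per thousand people of start-of-period
#' population per five-year period), the sex share of the total flow, and
#' distribution statistics over the full origin x destination key grid
#' (N, minimum, median, mean, maximum, standard deviation, proportion of zero
#' flows, and the mean and standard deviation of the non-zero flows).
#'
#' @param flows Flow table from [estimate_all()] (grid layout).
#' @param demo A [demographic_panel()] covering the same periods.
#' @param methods Method columns to summarise (default: those present).
#' @return A tibble, one row per sex x period x method.
#' @export
summarise_flows <- function(flows, demo, methods = NULL) {
  if (is.null(methods)) methods <- intersect(method_keys, names(flows))
  pops <- dplyr::summarise(
    dplyr::group_by(demo, .data$sex, .data$period_start),
    pop = sum(.data$pop_start), .groups = "drop")
  long <- tidyr::pivot_longer(flows, dplyr::all_of(methods),
                              names_to = "method", values_to = "flow")
  stats <- dplyr::summarise(
    dplyr::group_by(long, .data$sex, .data$period_start, .data$method),
    n = dplyr::n(), total = sum(.data$flow), min = min(.data$flow),
    median = stats::median(.data$flow), mean = mean(.data$flow),
    max = max(.data$flow), sd = stats::sd(.data$flow),
    prop_zero = mean(.data$flow == 0),
    mean_nonzero = ifelse(any(.data$flow > 0),
                          mean(.data$flow[.data$flow > 0]), NA_real_),
    sd_nonzero = ifelse(sum(.data$flow > 0) > 1,
                        stats::sd(.data$flow[.data$flow > 0]), NA_real_),
    .groups = "drop")
  stats <- dplyr::left_join(stats, pops, by = c("sex", "period_start"))
  stats$crude_rate <- ifelse(stats$pop > 0, stats$total / stats$pop * 1000,
                             NA_real_)
  shares <- dplyr::mutate(
    dplyr::group_by(stats, .data$period_start, .data$method),
    sex_share = .data$total / sum(.data$total))
  shares$sex_share[is.nan(shares$sex_share)] <- NA_real_
  dplyr::ungroup(shares)
}

#' Summary statistics of move-type flows
#'
#' Per sex, period, method and move type: total flows, crude migration rates
#' (per thousand of start-of-period population) and the share of each move
#' type in the method's total.
#'
#' @param move_types Move-type table from [estimate_all()].
#' @param demo A [demographic_panel()].
#' @param methods Method columns (default: accounting methods present).
#' @return A tibble, one row per sex x period x method x move type.
#' @export
summarise_move_types <- function(move_types, demo, methods = NULL) {
  if (is.null(methods)) {
    methods <- intersect(accounting_keys, names(move_types))
  }
  pops <- dplyr::summarise(
    dplyr::group_by(demo, .data$sex, .data$period_start),
    pop = sum(.data$pop_start), .groups = "drop")
  long <- tidyr::pivot_longer(move_types, dplyr::all_of(methods),
                              names_to = "method", values_to = "flow")
  tot <- dplyr::summarise(
    dplyr::group_by(long, .data$sex, .data$period_start, .data$method,
                    .data$move_type),
    total = sum(.data$flow), .groups = "drop")
  tot <- dplyr::left_join(tot, pops, by = c("sex", "period_start"))
  tot$crude_rate <- ifelse(tot$pop > 0, tot$total / tot$pop * 1000, NA_real_)
  shares <- dplyr::mutate(
    dplyr::group_by(tot, .data$sex, .data$period_start, .data$method),
    type_share = .data$total / sum(.data$total))
  shares$type_share[is.nan(shares$type_share)] <- NA_real_
  dplyr::ungroup(shares)
}

#' Write a flow estimate table in the published schema
#'
#' Writes `sex, orig, dest, year0` plus one column per method. Stock
#' differencing columns are written as integers when integer-valued; rates and
#' accounting columns are written to two decimal places. Rounding happens only
#' here, never inside the pipeline.
#'
#' @param flows Flow table from [estimate_all()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_flow_estimates <- function(flows, path) {
  out <- flows
  names(out)[names(out) == "period_start"] <- "year0"
  for (m in intersect(c("sd_drop_neg", "sd_rev_neg"), names(out))) {
    if (all(out[[m]] == round(out[[m]]))) out[[m]] <- as.integer(out[[m]])
  }
  for (m in intersect(c("mig_rate", accounting_keys), names(out))) {
    out[[m]] <- sprintf("%.2f", out[[m]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a move-type flow table in the published schema
#'
#' Writes `sex, move_type, orig, dest, year0` plus the accounting method
#' columns at two decimal places.
#'
#' @param move_types Move-type table from [estimate_all()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_move_types <- function(move_types, path) {
  out <- move_types
  names(out)[names(out) == "period_start"] <- "year0"
  for (m in intersect(accounting_keys, names(out))) {
    out[[m]] <- sprintf("%.2f", out[[m]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Net flows implied by a bilateral estimate table
#'
#' Per sex, period and country: total inflow minus total outflow. For the
#' closed demographic accounting methods this equals the net migration derived
#' from the demographic accounting equation.
#'
#' @param flows Flow table from [estimate_all()].
#' @param method Method column name.
#' @return A tibble `sex`, `period_start`, `country`, `net_flow`.
#' @export
implied_net_flows <- function(flows, method) {
  corr <- flows[flows$orig != flows$dest, ]
  inflow <- dplyr::summarise(
    dplyr::group_by(corr, .data$sex, .data$period_start,
                    country = .data$dest),
    inflow = sum(.data[[method]]), .groups = "drop")
  outflow <- dplyr::summarise(
    dplyr::group_by(corr, .data$sex, .data$period_start,
                    country = .data$orig),
    outflow = sum(.data[[method]]), .groups = "drop")
  out <- dplyr::full_join(inflow, outflow,
                          by = c("sex", "period_start", "country"))
  out$inflow[is.na(out$inflow)] <- 0
  out$outflow[is.na(out$outflow)] <- 0
  tibble::tibble(sex = out$sex, period_start = out$period_start,
                 country = out$country,
                 net_flow = out$inflow - out$outflow)
}
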
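#' Difference bilateral migrant stocks over a period
#'
#' Computes `diff = s_ij(t+5) - s_ij(t)` per sex for every foreign-born
#' bilateral cell (born in `orig`, residing in `dest`); home cells are
#' excluded. Differences may be negative.
#'
#' @param stocks A harmonised [stock_panel()] with both period endpoints.
#' @param period_start Start year of the five-year period.
#' @param period_length Years per period (default 5).
#' @return A tibble `sex`, `orig`, `dest`, `period_start`, `diff`.
#' @export
difference_stocks <- function(stocks, period_start, period_length = 5L) {
  t0 <- period_start
  t1 <- period_start + period_length
  for (tp in c(t0, t1)) {
    if (!any(stocks$year == tp)) {
      stop("stocks missing at time point ", tp, " for period starting ",
           period_start, call. = FALSE)
    }
  }
  fb <- stocks[stocks$birthplace != stocks$residence &
                 stocks$year %in% c(t0, t1), ]
  wide <- tidyr::pivot_wider(fb, names_from = "year", values_from = "stock",
                             values_fill = 0, names_prefix = "y")
  tibble::tibble(sex = wide$sex, orig = wide$birthplace,
                 dest = wide$residence,
                 period_start = as.integer(period_start),
                 diff = wide[[paste0("y", t1)]] - wide[[paste0("y", t0)]])
}

#' Stock differencing with negative differences dropped
#'
#' The flow from `orig` to `dest` is the stock difference when positive and
#' zero otherwise: `max(diff, 0)`.
#'
#' @param diffs Output of [difference_stocks()].
#' @return A tibble `sex`, `orig`, `dest`, `period_start`, `sd_drop_neg`.
#' @export
drop_negative <- function(diffs) {
  tibble::tibble(sex = diffs$sex, orig = diffs$orig, dest = diffs$dest,
                 period_start = diffs$period_start,
                 sd_drop_neg = pmax(diffs$diff, 0))
}

#' Stock differencing with negative differences reversed as return flows
#'
#' A negative difference in corridor `j -> i` is read as a return flow from
#' `j` to `i`: the flow `i -> j` is `max(diff_ij, 0) + max(-diff_ji, 0)`.
#' Simultaneous positive `diff_ij` and negative `diff_ji` are summed, not
#' netted.
#'
#' @param diffs Output of [difference_stocks()].
#' @return A tibble `sex`, `orig`, `dest`, `period_start`, `sd_rev_neg`.
#' @export
reverse_negative <- function(diffs) {
  transposed <- tibble::tibble(sex = diffs$sex, orig = diffs$dest,
                               dest = diffs$orig,
                               period_start = diffs$period_start,
                               rev_diff = diffs$diff)
  out <- dplyr::left_join(
    diffs, transposed, by = c("sex", "orig", "dest", "period_start"))
  out$rev_diff[is.na(out$rev_diff)] <- 0
  tibble::tibble(sex = out$sex, orig = out$orig, dest = out$dest,
                 period_start = out$period_start,
                 sd_rev_neg = pmax(out$diff, 0) + pmax(-out$rev_diff, 0))
}
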
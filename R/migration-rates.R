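#' Global flow total from absolute net migration
#'
#' The unknown global number of migrants in a period is approximated by the
#' sum over countries of the absolute value of net migration, per sex. Net
#' migration must first be derived with [derive_net_migration()].
#'
#' @param demo A [demographic_panel()] with a `net_migration` column.
#' @param halve_total If `TRUE`, divide the sum of absolute nets by two (each
#'   migrant contributes once to a positive and once to a negative net).
#'   Default `FALSE`: the total is used as defined.
#' @return A tibble `sex`, `period_start`, `G`.
#' @export
global_flow_total <- function(demo, halve_total = FALSE) {
  if (!"net_migration" %in% names(demo) || anyNA(demo$net_migration)) {
    stop("net_migration missing; call derive_net_migration() first",
         call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(demo, .data$sex, .data$period_start),
    G = sum(abs(.data$net_migration)), .groups = "drop")
  if (halve_total) out$G <- out$G / 2
  out
}

#' Rates-based flow estimation
#'
#' Allocates the global flow total `G` of a period across corridors in
#' proportion to the start-of-period bilateral stocks:
#' `flow_ij = s_ij(t) / sum(s(t)) * G`, over foreign-born cells of the
#' harmonised country set (home cells excluded). The denominator and `G` are
#' sex-specific.
#'
#' @param stocks A harmonised [stock_panel()].
#' @param totals Output of [global_flow_total()].
#' @param period_start Start year of the period.
#' @return A tibble `sex`, `orig`, `dest`, `period_start`, `mig_rate`.
#' @export
rate_allocate <- function(stocks, totals, period_start) {
  at_t0 <- stocks[stocks$year == period_start &
                    stocks$birthplace != stocks$residence, ]
  if (nrow(at_t0) == 0) {
    stop("no stocks at period start ", period_start, call. = FALSE)
  }
  g <- totals[totals$period_start == period_start, ]
  out <- list()
  for (s in unique(at_t0$sex)) {
    sub <- at_t0[at_t0$sex == s, ]
    G <- g$G[g$sex == s]
    if (length(G) != 1) {
      stop("no global total for sex ", s, " in period ", period_start,
           call. = FALSE)
    }
    denom <- sum(sub$stock)
    if (denom == 0) {
      if (G > 0) {
        stop("all stocks zero at period start ", period_start,
             " with positive global total: allocation undefined",
             call. = FALSE)
      }
      flow <- rep(0, nrow(sub))
    } else {
      flow <- sub$stock / denom * G
    }
    out[[s]] <- tibble::tibble(sex = s, orig = sub$birthplace,
                               dest = sub$residence,
                               period_start = as.integer(period_start),
                               mig_rate = flow)
  }
  dplyr::bind_rows(out)
}
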
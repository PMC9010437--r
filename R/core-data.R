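#' Construct and validate a bilateral migrant-stock panel
#'
#' A stock panel records, for each sex and time point, the number of persons
#' born in one country (`birthplace`) and residing in another (`residence`).
#' Time points sit on a five-year grid of mid-year instants (e.g. 1990, 1995,
#' ...). Only foreign-born cells (`birthplace != residence`) are expected in
#' input data; native home-cell stocks are derived from population totals with
#' [native_home_stock()].
#'
#' @param x A data frame with columns `sex` ("female"/"male", or "total"),
#'   `birthplace`, `residence` (country codes), `year` (integer time point) and
#'   `stock` (non-negative persons).
#' @return A validated tibble of class `stock_panel`.
#' @export
stock_panel <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("sex", "birthplace", "residence", "year", "stock")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("stock panel is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  x <- dplyr::select(x, dplyr::all_of(required))
  x$sex <- as.character(x$sex)
  x$birthplace <- as.character(x$birthplace)
  x$residence <- as.character(x$residence)
  x$year <- as.integer(x$year)
  x$stock <- as.numeric(x$stock)
  bad <- which(!is.finite(x$stock) | x$stock < 0)
  if (length(bad) > 0) {
    stop("negative or non-finite stock values at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  key <- paste(x$sex, x$birthplace, x$residence, x$year, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sex, birthplace, residence, year) keys in stock panel; first at row ",
         which(duplicated(key))[1], call. = FALSE)
  }
  class(x) <- c("stock_panel", class(x))
  x
}

#' @export
print.stock_panel <- function(x, ...) {
  cat(sprintf("<stock_panel> %d records | %d time points | %d countries\n",
              nrow(x), length(unique(x$year)),
              length(union(x$birthplace, x$residence))))
  NextMethod()
}

#' Read a bilateral migrant-stock panel from CSV
#'
#' Expects UTF-8 CSV with header `sex,birthplace,residence,year,stock` (an
#' `orig` column is accepted as an alias for `birthplace`).
#'
#' @param path Path to the CSV file.
#' @return A [stock_panel()].
#' @export
read_stocks <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("orig" %in% names(x) && !"birthplace" %in% names(x)) {
    names(x)[names(x) == "orig"] <- "birthplace"
  }
  stock_panel(x)
}

#' Write a stock panel to CSV
#'
#' Round-trips through [read_stocks()] without loss: integer-valued stocks are
#' written as integers, others at full precision.
#'
#' @param stocks A [stock_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stocks <- function(stocks, path) {
  readr::write_csv(stocks, path, progress = FALSE)
  invisible(path)
}

#' Construct and validate a demographic components panel
#'
#' One row per country, five-year period (labelled by its start year) and sex,
#' carrying start/end populations, deaths, total births (both sexes) and the
#' sex ratio at birth (male births per female birth). [derive_net_migration()]
#' adds the derived sex-specific births and net migration.
#'
#' @param x A data frame with columns `country`, `period_start`, `sex`,
#'   `pop_start`, `pop_end`, `deaths`, `births_total`, `srb`.
#' @return A validated tibble of class `demographic_panel`.
#' @export
demographic_panel <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("country", "period_start", "sex", "pop_start", "pop_end",
                "deaths", "births_total", "srb")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("demographic panel is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x$country <- as.character(x$country)
  x$period_start <- as.integer(x$period_start)
  x$sex <- as.character(x$sex)
  for (col in c("pop_start", "pop_end", "deaths", "births_total", "srb")) {
    x[[col]] <- as.numeric(x[[col]])
  }
  nonneg <- c("pop_start", "pop_end", "deaths", "births_total")
  for (col in nonneg) {
    if (any(!is.finite(x[[col]]) | x[[col]] < 0)) {
      stop("negative or non-finite values in '", col, "'", call. = FALSE)
    }
  }
  if (any(!is.finite(x$srb) | x$srb <= 0)) {
    stop("sex ratio at birth must be positive", call. = FALSE)
  }
  key <- paste(x$country, x$period_start, x$sex, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (country, period_start, sex) keys in demographic panel",
         call. = FALSE)
  }
  class(x) <- c("demographic_panel", class(x))
  x
}

#' @export
print.demographic_panel <- function(x, ...) {
  cat(sprintf("<demographic_panel> %d rows | %d countries | periods %s\n",
              nrow(x), length(unique(x$country)),
              paste(sort(unique(x$period_start)), collapse = ", ")))
  NextMethod()
}

#' Read a demographic components panel from CSV
#'
#' @param path Path to a CSV with header
#'   `country,period_start,sex,pop_start,pop_end,deaths,births_total,srb`.
#' @return A [demographic_panel()].
#' @export
read_demography <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  demographic_panel(x)
}

#' Write a demographic panel to CSV
#' @param demo A [demographic_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demography <- function(demo, path) {
  cols <- c("country", "period_start", "sex", "pop_start", "pop_end",
            "deaths", "births_total", "srb")
  readr::write_csv(demo[, cols], path, progress = FALSE)
  invisible(path)
}

#' Split total births by the sex ratio at birth
#'
#' Sex-specific births are obtained from the total number of births during a
#' period and the sex ratio at birth (SRB, male births per female birth):
#' `male = births_total * srb / (1 + srb)` and `female = births_total - male`.
#' No rounding is applied.
#'
#' @param births_total Total births (both sexes) during the period.
#' @param srb Sex ratio at birth, male births per female birth (> 0).
#' @return A list with numeric elements `female` and `male` (vectorised).
#' @export
#' @examples
#' split_births_by_sex(2050, 1.05) # 1000 female, 1050 male
split_births_by_sex <- function(births_total, srb) {
  if (any(!is.finite(births_total) | births_total < 0)) {
    stop("births_total must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(srb) | srb <= 0)) {
    stop("srb must be positive", call. = FALSE)
  }
  male <- births_total * srb / (1 + srb)
  list(female = births_total - male, male = male)
}

#' Derive sex-specific births and net migration
#'
#' Adds `births_sex` (via [split_births_by_sex()]) and `net_migration` from the
#' demographic accounting equation
#' `net = pop_end - pop_start - births_sex + deaths`, per country, period and
#' sex. For rows with `sex == "total"`, `births_sex` equals `births_total`.
#'
#' @param demo A [demographic_panel()].
#' @return The panel with `births_sex` and `net_migration` columns added.
#' @export
derive_net_migration <- function(demo) {
  needed <- c("pop_start", "pop_end", "deaths", "births_total", "srb")
  incomplete <- !stats::complete.cases(demo[, needed])
  if (any(incomplete)) {
    i <- which(incomplete)[1]
    stop(sprintf("missing demographic component for %s / %d / %s",
                 demo$country[i], demo$period_start[i], demo$sex[i]),
         call. = FALSE)
  }
  births <- split_births_by_sex(demo$births_total, demo$srb)
  demo$births_sex <- ifelse(demo$sex == "male", births$male,
                            ifelse(demo$sex == "female", births$female,
                                   demo$births_total))
  demo$net_migration <- demo$pop_end - demo$pop_start - demo$births_sex +
    demo$deaths
  demo
}

#' Harmonise stock and demographic panels to a common country set
#'
#' Per period, keeps only countries that (a) appear in the stock panel at both
#' the period's start and end time points, (b) appear in the demographic panel
#' for the period, and (c) have at least one non-zero bilateral stock at every
#' time point of the period (countries whose bilateral stocks are all zero at a
#' time point make several estimators infeasible and are dropped with a
#' warning). Stocks are densely completed over the retained country set:
#' corridors absent from the input are treated as stock 0.
#'
#' @param stocks A [stock_panel()] (foreign-born cells).
#' @param demo A [demographic_panel()].
#' @param period_length Years per period (default 5).
#' @return A list with elements `stocks` (dense, harmonised), `demo`
#'   (restricted) and `countries`, a tibble with columns `period_start` and
#'   `country` (the [country_panel] of active countries per period).
#' @export
harmonize <- function(stocks, demo, period_length = 5L) {
  periods <- sort(unique(demo$period_start))
  sexes <- sort(unique(stocks$sex))
  out_stocks <- list()
  out_demo <- list()
  out_countries <- list()
  for (p in periods) {
    t0 <- p
    t1 <- p + period_length
    at_t0 <- stocks[stocks$year == t0, ]
    at_t1 <- stocks[stocks$year == t1, ]
    in_stocks <- intersect(union(at_t0$birthplace, at_t0$residence),
                           union(at_t1$birthplace, at_t1$residence))
    in_demo <- unique(demo$country[demo$period_start == p])
    keep <- intersect(in_stocks, in_demo)
    if (length(keep) == 0) {
      stop("no countries common to stocks and demographics in period ", p,
           call. = FALSE)
    }
    # drop countries with all-zero bilateral stocks at either endpoint
    for (tp in c(t0, t1)) {
      at_tp <- stocks[stocks$year == tp &
                        (stocks$birthplace %in% keep | stocks$residence %in% keep), ]
      for (cc in keep) {
        tot <- sum(at_tp$stock[at_tp$birthplace == cc | at_tp$residence == cc])
        if (tot == 0) {
          warning(sprintf(
            "dropping %s in period %d: all bilateral stocks zero at %d",
            cc, p, tp), call. = FALSE)
          keep <- setdiff(keep, cc)
        }
      }
    }
    if (length(keep) == 0) {
      stop("no countries with non-zero stocks in period ", p, call. = FALSE)
    }
    keep <- sort(keep)
    grid <- tidyr::expand_grid(sex = sexes, birthplace = keep,
                               residence = keep, year = c(t0, t1))
    grid <- grid[grid$birthplace != grid$residence, ]
    sub <- stocks[stocks$year %in% c(t0, t1) &
                    stocks$birthplace %in% keep &
                    stocks$residence %in% keep &
                    stocks$birthplace != stocks$residence, ]
    dense <- dplyr::left_join(
      grid, sub, by = c("sex", "birthplace", "residence", "year"))
    dense$stock[is.na(dense$stock)] <- 0
    out_stocks[[as.character(p)]] <- dense
    out_demo[[as.character(p)]] <-
      demo[demo$period_start == p & demo$country %in% keep, ]
    out_countries[[as.character(p)]] <-
      tibble::tibble(period_start = as.integer(p), country = keep)
  }
  dense_all <- dplyr::bind_rows(out_stocks)
  # a time point shared by two periods appears twice in the union; keep one
  dense_all <- dplyr::summarise(
    dplyr::group_by(dense_all, .data$sex, .data$birthplace, .data$residence,
                    .data$year),
    stock = dplyr::first(.data$stock), .groups = "drop")
  list(stocks = stock_panel(dense_all),
       demo = demographic_panel(dplyr::bind_rows(out_demo)),
       countries = dplyr::bind_rows(out_countries))
}

#' Population totals at a time point
#'
#' Looks up the population of each country and sex at a mid-year time point
#' from the demographic panel: the start population of the period beginning at
#' `time_point`, or failing that the end population of the period ending there.
#'
#' @param demo A [demographic_panel()].
#' @param time_point Year on the five-year grid.
#' @param period_length Years per period (default 5).
#' @return A tibble `country`, `sex`, `population`.
#' @export
population_at <- function(demo, time_point, period_length = 5L) {
  as_start <- demo[demo$period_start == time_point, ]
  if (nrow(as_start) > 0) {
    return(tibble::tibble(country = as_start$country, sex = as_start$sex,
                          population = as_start$pop_start))
  }
  as_end <- demo[demo$period_start == time_point - period_length, ]
  if (nrow(as_end) > 0) {
    return(tibble::tibble(country = as_end$country, sex = as_end$sex,
                          population = as_end$pop_end))
  }
  stop("no demographic data covering time point ", time_point, call. = FALSE)
}

#' Derive native home-cell stocks
#'
#' The bilateral stock table carries only foreign-born cells. The native-born
#' population residing at home (the home cell `s_kk`) is the country's total
#' population minus its foreign-born residents. Negative values signal
#' inconsistent inputs and are clamped to zero with a warning.
#'
#' @param stocks A harmonised [stock_panel()].
#' @param demo A [demographic_panel()].
#' @param time_point Year on the five-year grid.
#' @return A tibble `sex`, `country`, `home_stock`.
#' @export
native_home_stock <- function(stocks, demo, time_point) {
  at_tp <- stocks[stocks$year == time_point &
                    stocks$birthplace != stocks$residence, ]
  fb <- dplyr::summarise(
    dplyr::group_by(at_tp, .data$sex, country = .data$residence),
    foreign_born = sum(.data$stock), .groups = "drop")
  pop <- population_at(demo, time_point)
  out <- dplyr::left_join(pop, fb, by = c("country", "sex"))
  out$foreign_born[is.na(out$foreign_born)] <- 0
  out$home_stock <- out$population - out$foreign_born
  neg <- out$home_stock < 0
  if (any(neg)) {
    warning(sprintf(
      "clamping %d negative native home stock(s) to 0 at %d (first: %s %s)",
      sum(neg), time_point, out$sex[neg][1], out$country[neg][1]),
      call. = FALSE)
    out$home_stock[neg] <- 0
  }
  tibble::tibble(sex = out$sex, country = out$country,
                 home_stock = out$home_stock)
}

#' Country panel with the dimensions of the published global estimates
#'
#' Builds a country panel matching the coverage of the published global flow
#' estimates: 197 countries in the four periods 1990-2005 and 200 in the two
#' periods 2010 and 2015. Codes are synthetic placeholders (C001...C200); the
#' real country list uses named 3-letter codes, but all key-space arithmetic
#' depends only on the counts.
#'
#' @return A tibble `period_start`, `country`.
#' @export
study_country_panel <- function() {
  codes <- sprintf("C%03d", seq_len(200))
  early <- tidyr::expand_grid(period_start = c(1990L, 1995L, 2000L, 2005L),
                              country = codes[seq_len(197)])
  late <- tidyr::expand_grid(period_start = c(2010L, 2015L), country = codes)
  dplyr::bind_rows(early, late)
}

#' Key-space sizes implied by a country panel
#'
#' The published estimates keep one row per origin x destination x period cell
#' (including origin = destination), so the corridor key space per sex is
#' `sum(n_countries^2)` over periods; the flow file doubles it over two sexes
#' and the move-type file carries three move types per flow row.
#'
#' @param countries A tibble `period_start`, `country` (e.g. from
#'   [harmonize()] or [study_country_panel()]).
#' @return A list with integer elements `corridor_cells` (per sex),
#'   `flow_file_rows`, `move_type_file_rows` and `country_periods`.
#' @export
key_space <- function(countries) {
  n_per <- table(countries$period_start)
  cells <- sum(as.numeric(n_per)^2)
  list(corridor_cells = as.integer(cells),
       flow_file_rows = as.integer(2 * cells),
       move_type_file_rows = as.integer(2 * 3 * cells),
       country_periods = as.integer(sum(as.numeric(n_per))))
}
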
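#' Configuration for a synthetic migration world
#'
#' Defines the simulation conditions for [generate_world()]. Rates are per five-year
#' period: `birth_rate` and `death_rate` are births/deaths per person of
#' start-of-period population, `migration_intensity` is the out-migration
#' transition probability (share of a country's residents who reside elsewhere
#' at the end of the period). `initial_diaspora` is the share of each country's
#' born population living abroad at the first time point.
#'
#' @param n_countries Number of countries (>= 2).
#' @param n_periods Number of five-year periods (>= 1).
#' @param seed Integer master seed; identical seeds give identical worlds.
#' @param base_pop_range Range of per-sex born populations per country.
#' @param migration_intensity Out-migration transition probability in `[0, 1)`.
#' @param birth_rate,death_rate Per-period demographic rates in `[0, 1)`.
#' @param srb_range Interval for the sex ratio at birth (male per female).
#' @param initial_diaspora Initial share of born population abroad, in `[0, 1)`.
#' @param start_year First time point (mid-year, five-year grid).
#' @return A `world_config` list.
#' @export
world_config <- function(n_countries = 10L, n_periods = 3L, seed = 42L,
                         base_pop_range = c(5e5, 5e6),
                         migration_intensity = 0.02,
                         birth_rate = 0.10, death_rate = 0.07,
                         srb_range = c(1.04, 1.07),
                         initial_diaspora = 0.05,
                         start_year = 1990L) {
  if (n_countries < 2) stop("n_countries must be >= 2", call. = FALSE)
  if (n_periods < 1) stop("n_periods must be >= 1", call. = FALSE)
  rates <- c(migration_intensity, birth_rate, death_rate, initial_diaspora)
  if (any(rates < 0 | rates >= 1)) {
    stop("rates must lie in [0, 1)", call. = FALSE)
  }
  if (any(srb_range <= 0)) stop("srb_range must be positive", call. = FALSE)
  structure(list(n_countries = as.integer(n_countries),
                 n_periods = as.integer(n_periods),
                 seed = as.integer(seed),
                 base_pop_range = base_pop_range,
                 migration_intensity = migration_intensity,
                 birth_rate = birth_rate, death_rate = death_rate,
                 srb_range = srb_range,
                 initial_diaspora = initial_diaspora,
                 start_year = as.integer(start_year)),
            class = "world_config")
}

#' Generate a demographically consistent synthetic world
#'
#' Simulates bilateral migrant stocks, demographic components and the true
#' five-year flows that produced them. Within each period and sex: deaths are
#' removed from start-of-period stocks proportionally across birthplace within
#' each residence; true corridor flows (log-normal gravity-like intensities)
#' then move survivors between residences, carrying the residence's birthplace
#' composition; sex-specific births are finally added to the home cell of the
#' end-of-period stocks. Populations therefore satisfy the demographic
#' accounting equation `pop_end = pop_start + births - deaths + net` exactly,
#' with net migration equal to the net of the sampled true flows.
#'
#' @param cfg A [world_config()].
#' @return A list with `stocks` (a [stock_panel()] of foreign-born cells at
#'   every time point), `demo` (a [demographic_panel()]) and `flows` (a tibble
#'   `sex`, `orig`, `dest`, `period_start`, `flow` of the true flows).
#' @export
generate_world <- function(cfg = world_config()) {
  stopifnot(inherits(cfg, "world_config"))
  n <- cfg$n_countries
  codes <- sprintf("C%03d", seq_len(n))
  sexes <- c("female", "male")
  years <- cfg$start_year + 5L * (0:cfg$n_periods)

  # one RNG stream per (sex, period) plus shared per-period and init streams,
  # all derived from the master seed
  set.seed(cfg$seed)
  n_streams <- 2L + 2L * cfg$n_periods + cfg$n_periods
  stream_seeds <- sample.int(.Machine$integer.max, n_streams)
  seed_init <- stream_seeds[1:2]
  seed_sexper <- matrix(stream_seeds[2 + seq_len(2 * cfg$n_periods)],
                        nrow = 2, ncol = cfg$n_periods)
  seed_shared <- stream_seeds[2 + 2 * cfg$n_periods + seq_len(cfg$n_periods)]

  # initial stocks: matrix S[k, j] = born in k, residing in j, per sex
  S <- list()
  for (s in 1:2) {
    set.seed(seed_init[s])
    born <- stats::runif(n, cfg$base_pop_range[1], cfg$base_pop_range[2])
    m <- matrix(0, n, n, dimnames = list(codes, codes))
    for (k in seq_len(n)) {
      abroad <- cfg$initial_diaspora * born[k]
      m[k, k] <- born[k] - abroad
      if (n > 1 && abroad > 0) {
        w <- stats::rlnorm(n - 1, meanlog = 0, sdlog = 1)
        m[k, -k] <- abroad * w / sum(w)
      }
    }
    S[[s]] <- m
  }

  stock_rows <- list()
  demo_rows <- list()
  flow_rows <- list()
  snapshot <- function(m, sx, yr) {
    idx <- which(row(m) != col(m), arr.ind = TRUE)
    tibble::tibble(sex = sx, birthplace = codes[idx[, 1]],
                   residence = codes[idx[, 2]], year = yr,
                   stock = m[idx])
  }
  for (s in 1:2) stock_rows[[length(stock_rows) + 1]] <-
    snapshot(S[[s]], sexes[s], years[1])

  for (p in seq_len(cfg$n_periods)) {
    t0 <- years[p]
    pop_start <- lapply(S, colSums)
    deaths <- list()
    flows <- list()
    for (s in 1:2) {
      set.seed(seed_sexper[s, p])
      D <- cfg$death_rate * pop_start[[s]] * stats::runif(n, 0.9, 1.1)
      if (any(D > pop_start[[s]])) {
        stop("infeasible config: deaths exceed population in period ", t0,
             call. = FALSE)
      }
      surv_frac <- ifelse(pop_start[[s]] > 0, 1 - D / pop_start[[s]], 1)
      S[[s]] <- sweep(S[[s]], 2, surv_frac, "*")
      deaths[[s]] <- D

      resid <- colSums(S[[s]])
      f <- matrix(0, n, n, dimnames = list(codes, codes))
      out_total <- cfg$migration_intensity * resid * stats::runif(n, 0.8, 1.2)
      w <- matrix(stats::rlnorm(n * n, 0, 1), n, n)
      diag(w) <- 0
      for (i in seq_len(n)) {
        if (out_total[i] > 0 && sum(w[i, ]) > 0) {
          f[i, ] <- out_total[i] * w[i, ] / sum(w[i, ])
        }
      }
      if (any(rowSums(f) > resid + 1e-9)) {
        stop("infeasible config: flows exceed residents in period ", t0,
             call. = FALSE)
      }
      # movers carry the origin residence's birthplace composition
      new_S <- S[[s]]
      for (i in seq_len(n)) {
        if (resid[i] > 0) {
          leave_frac <- sum(f[i, ]) / resid[i]
          comp <- S[[s]][, i] / resid[i]
          new_S[, i] <- new_S[, i] - S[[s]][, i] * leave_frac
          for (j in seq_len(n)) {
            if (f[i, j] > 0) new_S[, j] <- new_S[, j] + comp * f[i, j]
          }
        }
      }
      S[[s]] <- new_S
      flows[[s]] <- f
    }

    set.seed(seed_shared[p])
    births_total <- cfg$birth_rate * (pop_start[[1]] + pop_start[[2]]) *
      stats::runif(n, 0.9, 1.1)
    srb <- stats::runif(n, cfg$srb_range[1], cfg$srb_range[2])
    births <- split_births_by_sex(births_total, srb)
    for (s in 1:2) {
      b <- if (s == 1) births$female else births$male
      diag(S[[s]]) <- diag(S[[s]]) + b
      pop_end <- colSums(S[[s]])
      demo_rows[[length(demo_rows) + 1]] <- tibble::tibble(
        country = codes, period_start = t0, sex = sexes[s],
        pop_start = pop_start[[s]], pop_end = pop_end,
        deaths = deaths[[s]], births_total = births_total, srb = srb)
      idx <- which(row(flows[[s]]) != col(flows[[s]]), arr.ind = TRUE)
      flow_rows[[length(flow_rows) + 1]] <- tibble::tibble(
        sex = sexes[s], orig = codes[idx[, 1]], dest = codes[idx[, 2]],
        period_start = t0, flow = flows[[s]][idx])
      stock_rows[[length(stock_rows) + 1]] <-
        snapshot(S[[s]], sexes[s], years[p + 1])
    }
  }

  list(stocks = stock_panel(dplyr::bind_rows(stock_rows)),
       demo = demographic_panel(dplyr::bind_rows(demo_rows)),
       flows = dplyr::bind_rows(flow_rows))
}

#' Two-country Puerto Rico / USA fixture
#'
#' A minimal stock and demography pair embedding the 2010-2015 changes in the
#' Puerto Rican-born population of the USA reported in the UN DESA stock data:
#' the total corridor stock fell by 15,028 while the female stock fell by
#' 119,357 and the male stock rose by 104,329. The corridor illustrates how a
#' sex-specific decomposition of stock differencing can recover a large male
#' flow that the total-stock difference hides. Baseline stock levels and the
#' demographic panel are synthetic round numbers; only the changes are
#' data-derived.
#'
#' @return A list with `stocks` (a [stock_panel()]) and `demo`
#'   (a [demographic_panel()]).
#' @export
puerto_rico_fixture <- function() {
  female_change <- -119357
  male_change <- -15028 - female_change # +104,329
  stocks <- tibble::tibble(
    sex = rep(c("female", "male"), each = 4),
    birthplace = rep(c("PRI", "PRI", "USA", "USA"), 2),
    residence = rep(c("USA", "USA", "PRI", "PRI"), 2),
    year = rep(c(2010L, 2015L), 4),
    stock = c(1600000, 1600000 + female_change, 200000, 200000,
              1300000, 1300000 + male_change, 150000, 150000))
  demo <- tibble::tibble(
    country = rep(c("PRI", "USA"), each = 2),
    period_start = 2010L,
    sex = rep(c("female", "male"), 2),
    pop_start = c(1900000, 1800000, 157000000, 152000000),
    pop_end = c(1750000, 1780000, 159000000, 154000000),
    deaths = c(80000, 85000, 6500000, 6600000),
    births_total = c(210000, 210000, 19800000, 19800000),
    srb = c(1.05, 1.05, 1.05, 1.05))
  list(stocks = stock_panel(stocks), demo = demographic_panel(demo))
}
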
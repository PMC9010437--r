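# shared fixtures built in code

tiny_world <- function(n_countries = 5, n_periods = 2, seed = 99, ...) {
  generate_world(world_config(n_countries = n_countries,
                              n_periods = n_periods, seed = seed, ...))
}

# hand-built adjusted pair, bypassing adjust_stocks, for margin-level tests
make_pair <- function(start, end, balanced = "none", sex = "female",
                      period_start = 1990L) {
  countries <- sprintf("C%02d", seq_len(nrow(start)))
  dimnames(start) <- dimnames(end) <- list(countries, countries)
  structure(list(start = start, end = end, countries = countries,
                 sex = sex, period_start = period_start,
                 balanced = balanced, out_origin = NULL, out_dest = NULL),
            class = "adjusted_stock_pair")
}

# random pair whose per-birthplace start/end totals already agree (closed)
random_closed_pair <- function(n, seed) {
  set.seed(seed)
  start <- matrix(stats::runif(n * n, 1, 100), n, n)
  end <- matrix(stats::runif(n * n, 0.1, 1), n, n)
  end <- end * (rowSums(start) / rowSums(end))
  make_pair(start, end, balanced = "closed")
}

# two-country, two-time-point stock/demography toy used across core tests:
# residence A holds 60 native-born and 40 born in B; B holds 80 natives and
# 20 born in A
toy_inputs <- function() {
  stocks <- stock_panel(tibble::tibble(
    sex = "female",
    birthplace = rep(c("B", "A"), 2),
    residence = rep(c("A", "B"), 2),
    year = rep(c(1990L, 1995L), each = 2),
    stock = c(40, 20, 40, 20)))
  demo <- demographic_panel(tibble::tibble(
    country = c("A", "B"),
    period_start = 1990L,
    sex = "female",
    pop_start = c(100, 100),
    pop_end = c(100, 100),
    deaths = c(10, 0),
    births_total = c(0, 41), # 20 female + 21 male at srb 1.05
    srb = 1.05))
  list(stocks = stocks, demo = demo)
}
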
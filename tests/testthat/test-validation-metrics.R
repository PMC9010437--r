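test_that("five-year equivalents are five times the mean of available years", {
  rep_full <- tibble::tibble(orig = "A", dest = "B", year = 1990:1994,
                             flow = c(10, 20, 30, 40, 50))
  eq <- five_year_equivalent(rep_full, 1990L)
  expect_equal(eq$flow_5yr, 150)
  expect_equal(eq$n_years, 5L)
  # partial coverage still averages over what is available
  eq2 <- five_year_equivalent(rep_full[1:2, ], 1990L)
  expect_equal(eq2$flow_5yr, 75)
  # corridors with no data in the period are omitted, not zero-filled
  eq3 <- five_year_equivalent(rep_full, c(1990L, 1995L))
  expect_equal(nrow(eq3), 1)
  expect_equal(eq3$period_start, 1990L)
  # linearity in the annual flows
  scaled <- rep_full
  scaled$flow <- scaled$flow * 3.5
  expect_equal(five_year_equivalent(scaled, 1990L)$flow_5yr, 150 * 3.5)
  expect_error(five_year_equivalent(dplyr::mutate(rep_full, flow = -flow),
                                    1990L), "non-negative")
})

fake_est <- function() {
  grid <- expand.grid(orig = c("A", "B", "C"), dest = c("A", "B", "C"),
                      stringsAsFactors = FALSE)
  grid <- grid[grid$orig != grid$dest, ]
  set.seed(12)
  tibble::tibble(sex = "female", orig = grid$orig, dest = grid$dest,
                 period_start = 1990L, flow = round(runif(nrow(grid), 1, 100)))
}

fake_demo <- function() {
  demographic_panel(tibble::tibble(
    country = c("A", "B", "C"), period_start = 1990L, sex = "female",
    pop_start = c(1e4, 2e4, 3e4), pop_end = c(1e4, 2e4, 3e4),
    deaths = 0, births_total = 0, srb = 1.05))
}

test_that("measures pair up exactly when estimates equal reports", {
  est <- fake_est()
  ref <- est
  names(ref)[names(ref) == "flow"] <- "flow_5yr"
  mv <- compute_measures(est, ref, fake_demo())
  expect_named(mv, c("count", "log_count", "proportion_in", "proportion_out",
                     "imm_rate", "emi_rate", "net_count"))
  for (m in names(mv)) {
    expect_equal(mv[[m]]$est, mv[[m]]$ref, tolerance = 1e-12)
    expect_equal(suppressWarnings(pearson_cor(mv[[m]])), 1, tolerance = 1e-9)
  }
  # proportions into each destination sum to one
  pin <- mv$proportion_in
  sums <- tapply(pin$est, pin$dest, sum)
  expect_equal(as.numeric(sums), rep(1, 3), tolerance = 1e-12)
})

test_that("log measure zero handling follows the configured policy", {
  est <- fake_est()
  est$flow[1] <- 0
  ref <- fake_est()
  names(ref)[names(ref) == "flow"] <- "flow_5yr"
  drop <- compute_measures(est, ref, fake_demo(), log_zero = "drop")
  expect_equal(nrow(drop$log_count), nrow(est) - 1)
  add1 <- compute_measures(est, ref, fake_demo(), log_zero = "add1")
  expect_equal(nrow(add1$log_count), nrow(est))
  expect_equal(add1$log_count$est[1], 0) # log(0 + 1)
})

test_that("pearson correlation handles signals and degenerate input", {
  expect_equal(pearson_cor(tibble::tibble(est = 1:5, ref = 1:5)), 1)
  expect_equal(pearson_cor(tibble::tibble(est = 1:5, ref = 5:1)), -1)
  x <- c(2, 4, 6, 9, 14)
  y <- c(1, 3, 2, 8, 11)
  # textbook product-moment formula as oracle
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(tibble::tibble(est = x, ref = y)), r_oracle)
  expect_warning(r0 <- pearson_cor(tibble::tibble(est = rep(1, 4), ref = 1:4)),
                 "zero variance")
  expect_true(is.na(r0))
  expect_warning(pearson_cor(tibble::tibble(est = 1, ref = 1)), "2 pairs")
})

test_that("net counts of a closed synthetic world correlate perfectly with input nets", {
  w <- tiny_world(n_countries = 6, n_periods = 1, seed = 77)
  res <- estimate_all(w$stocks, w$demo, methods = "da_min_closed",
                      layout = "corridor")
  est <- res$flows
  names(est)[names(est) == "da_min_closed"] <- "flow"
  # reported set = the world's true flows (full coverage)
  ref <- w$flows
  names(ref)[names(ref) == "flow"] <- "flow_5yr"
  demo_d <- derive_net_migration(w$demo)
  mv <- compute_measures(est, ref, demo_d)
  net <- dplyr::inner_join(
    mv$net_count,
    demo_d[, c("sex", "country", "period_start", "net_migration")],
    by = c("sex", "country", "period_start"))
  expect_equal(net$est, net$net_migration, tolerance = 1e-6)
  expect_equal(net$ref, net$net_migration, tolerance = 1e-6)
  expect_lt(abs(pearson_cor(mv$net_count) - 1), 1e-9)
})

test_that("discrepancy summaries match a sort-based percentile oracle", {
  est <- fake_est()
  wide_t <- est
  names(wide_t)[names(wide_t) == "flow"] <- "sd_drop_neg"
  # a method against itself is identically zero
  z <- discrepancy_summary(wide_t, wide_t)
  expect_equal(unlist(z[, c("mean", "median", "sd", "iqr", "idr", "ipr99",
                            "min", "max")]),
               rep(0, 8), ignore_attr = TRUE)

  set.seed(9)
  wide_s <- wide_t
  wide_s$sd_drop_neg <- wide_s$sd_drop_neg + round(rnorm(nrow(wide_s), 0, 20))
  ds <- discrepancy_summary(wide_t, wide_s)
  d <- wide_t$sd_drop_neg - wide_s$sd_drop_neg
  expect_equal(ds$mean, mean(d))
  expect_equal(ds$min, min(d))
  expect_equal(ds$max, max(d))
  expect_equal(ds$iqr, quantile_oracle(d, 0.75) - quantile_oracle(d, 0.25))
  expect_equal(ds$idr, quantile_oracle(d, 0.90) - quantile_oracle(d, 0.10))
  expect_equal(ds$ipr99,
               quantile_oracle(d, 0.995) - quantile_oracle(d, 0.005))
  expect_true(ds$min <= ds$median && ds$median <= ds$max)
  expect_true(ds$iqr <= ds$idr && ds$idr <= ds$ipr99)

  mismatched <- wide_s[-1, ]
  expect_error(discrepancy_summary(wide_t, mismatched), "do not match")
})

test_that("correlation tables are tidy across measures", {
  w <- tiny_world(n_countries = 5, n_periods = 1, seed = 13)
  res <- estimate_all(w$stocks, w$demo, methods = "sd_drop_neg",
                      layout = "corridor")
  est <- res$flows
  names(est)[names(est) == "sd_drop_neg"] <- "flow"
  ref <- w$flows
  names(ref)[names(ref) == "flow"] <- "flow_5yr"
  demo_d <- derive_net_migration(w$demo)
  tab <- correlate_measures(est, ref, demo_d, method = "sd_drop_neg",
                            source = "truth")
  expect_setequal(unique(tab$sex), c("female", "male"))
  expect_equal(nrow(tab), 2 * 7)
  expect_true(all(is.na(tab$r) | (tab$r >= -1 & tab$r <= 1)))
})
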
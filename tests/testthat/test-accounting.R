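test_that("stock adjustment removes deaths proportionally and births from home cells", {
  toy <- toy_inputs()
  # no births or deaths: adjusted equals raw stocks with derived home cells
  demo0 <- toy$demo
  demo0$deaths <- 0
  demo0$births_total <- 0
  pair0 <- adjust_stocks(toy$stocks, demographic_panel(demo0), 1990L, "female")
  expect_equal(pair0$start["A", "A"], 60)
  expect_equal(pair0$start["B", "A"], 40)
  expect_equal(pair0$start, pair0$end)

  # deaths 10 in A with residents {60 born A, 40 born B} -> {54, 36}
  pair <- adjust_stocks(toy$stocks, toy$demo, 1990L, "female")
  expect_equal(pair$start["A", "A"], 54)
  expect_equal(pair$start["B", "A"], 36)
  expect_equal(pair$start["A", "B"], 20) # no deaths in B
  # 20 female births in B reduce the end home cell from 80 to 60
  expect_equal(pair$end["B", "B"], 60)
  expect_equal(pair$end["A", "A"], 60) # no births in A
})

test_that("open balancing absorbs per-birthplace discrepancies in OUT margins", {
  start <- rbind(c(50, 40), c(30, 40))
  end_bal <- rbind(c(45, 45), c(35, 35))
  pair <- balance_open(make_pair(start, end_bal))
  expect_equal(unname(pair$out_origin), c(0, 0)) # already balanced
  expect_equal(unname(pair$out_dest), c(0, 0))

  end <- rbind(c(60, 50), c(30, 60)) # row totals 110, 90 vs start 90, 70
  pair2 <- balance_open(make_pair(start, end))
  expect_equal(unname(pair2$out_origin), c(20, 20)) # end exceeds start
  # mirrored discrepancy lands on the OUT destination
  pair3 <- balance_open(make_pair(end, start))
  expect_equal(unname(pair3$out_dest), c(20, 20))
  # extended totals balance exactly per birthplace
  expect_equal(rowSums(pair2$start) + pair2$out_origin,
               rowSums(pair2$end) + pair2$out_dest)
})

test_that("closed balancing scales both tables to the mid-point total", {
  start <- rbind(c(50, 40), c(30, 40))
  pair_id <- balance_closed(make_pair(start, start))
  expect_equal(pair_id$start, pair_id$end) # R = C leaves tables untouched
  expect_equal(unname(rowSums(pair_id$start)), c(90, 70))

  end <- rbind(c(60, 50), c(30, 60))
  pair <- balance_closed(make_pair(start, end))
  expect_equal(unname(rowSums(pair$start)), c(100, 80)) # mid-points
  expect_equal(rowSums(pair$start), rowSums(pair$end))
  expect_equal(unname(pair$start[1, ]), start[1, ] * 10 / 9)
  expect_equal(unname(pair$end[1, ]), end[1, ] * 10 / 11)

  bad <- make_pair(rbind(c(0, 0), c(30, 40)), end)
  expect_error(balance_closed(bad), "exactly one")

  for (seed in 1:10) {
    p <- balance_closed(random_closed_pair(5, seed))
    expect_equal(unname(rowSums(p$start) / rowSums(p$end)), rep(1, 5),
                 tolerance = 1e-12)
  }
})

test_that("minimisation imputation maximises stayers and fits residual margins", {
  # forced example: rows (50,30,20), cols (40,40,20) leave a single free cell
  start <- rbind(c(50, 30, 20), matrix(0, 2, 3))
  end <- rbind(c(40, 40, 20), matrix(0, 2, 3))
  pair <- make_pair(start, end, balanced = "closed")
  arr <- impute_min(pair)
  slice <- unclass(arr)[, , 1]
  expect_equal(diag(slice), c(40, 30, 20), ignore_attr = TRUE)
  expect_equal(slice[1, 2], 10)
  expect_equal(sum(slice) - sum(diag(slice)), 10) # only one off-diagonal cell

  # equal margins put all mass on the diagonal: zero migration
  pair_eq <- make_pair(start, start, balanced = "closed")
  arr_eq <- impute_min(pair_eq)
  expect_equal(sum(flows_from_array(arr_eq)$flow), 0)

  # random balanced margins are reproduced to the IPF tolerance
  for (seed in 1:10) {
    p <- random_closed_pair(4, seed)
    a <- unclass(impute_min(p))
    for (k in 1:4) {
      expect_lt(max(abs(rowSums(a[, , k]) - p$start[k, ])), 1e-5)
      expect_lt(max(abs(colSums(a[, , k]) - p$end[k, ])), 1e-5)
      expect_equal(diag(a[, , k]), pmin(p$start[k, ], p$end[k, ]),
                   ignore_attr = TRUE, tolerance = 1e-9)
    }
  }
  expect_error(impute_min(make_pair(start, end)), "balanced")
})

test_that("open-system imputation balances through the OUT index", {
  set.seed(2)
  start <- matrix(runif(9, 10, 100), 3, 3)
  end <- matrix(runif(9, 10, 100), 3, 3)
  pair <- balance_open(make_pair(start, end))
  arr <- impute_min(pair)
  a <- unclass(arr)
  expect_equal(dim(a), c(4, 4, 3))
  for (k in 1:3) {
    expect_lt(max(abs(rowSums(a[, , k]) -
                        c(start[k, ], pair$out_origin[k]))), 1e-5)
    expect_lt(max(abs(colSums(a[, , k]) -
                        c(end[k, ], pair$out_dest[k]))), 1e-5)
    expect_equal(a[4, 4, k], 0) # OUT x OUT structurally zero
  }
})

test_that("independent imputation equals the outer product and its IPF limit", {
  start <- rbind(c(10, 0), c(0, 0))
  end <- rbind(c(5, 5), c(0, 0))
  pair <- make_pair(start, end, balanced = "closed")
  arr <- impute_indep(pair)
  expect_equal(unclass(arr)[, , 1], rbind(c(5, 5), c(0, 0)),
               ignore_attr = TRUE)
  expect_equal(unclass(arr)[, , 2], matrix(0, 2, 2), ignore_attr = TRUE)

  for (seed in 1:5) {
    p <- random_closed_pair(4, seed + 50)
    a <- unclass(impute_indep(p))
    for (k in 1:4) {
      iter <- ipf_fit(matrix(1, 4, 4), p$start[k, ], p$end[k, ], tol = 1e-10)
      expect_equal(a[, , k], iter, ignore_attr = TRUE, tolerance = 1e-7)
    }
  }
  expect_error(impute_indep(balance_open(make_pair(start, end))), "closed")
})

test_that("pseudo-Bayesian combination is the stated cellwise weighting", {
  p <- random_closed_pair(3, 7)
  arr_min <- impute_min(p)
  arr_indep <- impute_indep(p)
  pb <- pseudo_bayes(arr_min, arr_indep)
  expect_equal(unclass(pb), 0.87 * unclass(arr_min) + 0.13 * unclass(arr_indep),
               ignore_attr = TRUE)
  # cells 100 (min) and 200 (indep) combine to 113 under the published weight
  a1 <- arr_min
  a1[1, 2, 1] <- 100
  a2 <- arr_indep
  a2[1, 2, 1] <- 200
  expect_equal(unclass(pseudo_bayes(a1, a2))[1, 2, 1], 113)
  # boundary weights reproduce each imputation
  expect_equal(unclass(pseudo_bayes(arr_min, arr_indep, w1 = 1)),
               unclass(arr_min), ignore_attr = TRUE)
  expect_equal(unclass(pseudo_bayes(arr_min, arr_min, w1 = 0.4)),
               unclass(arr_min), ignore_attr = TRUE)
  p2 <- random_closed_pair(4, 8)
  expect_error(pseudo_bayes(arr_min, impute_indep(p2)), "shapes")
})

test_that("bilateral flows are birthplace sums over off-diagonal cells", {
  # hand-built 2-country, 2-birthplace array
  a <- array(0, c(2, 2, 2))
  a[1, 2, 1] <- 3 # born 1, moved 1 -> 2 (outward)
  a[1, 2, 2] <- 4 # born 2, moved 1 -> 2 (return)
  a[1, 1, 1] <- 100 # stayers are excluded from flows
  arr <- structure(a, countries = c("A", "B"), sex = "female",
                   period_start = 1990L, system = "closed",
                   imputation = "min",
                   class = c("birthplace_flow_array", "array"))
  fl <- flows_from_array(arr)
  expect_equal(fl$flow[fl$orig == "A" & fl$dest == "B"], 7)
  expect_equal(fl$flow[fl$orig == "B" & fl$dest == "A"], 0)
  mt <- move_type_decompose(arr)
  ab <- mt[mt$orig == "A" & mt$dest == "B", ]
  expect_equal(ab$flow[ab$move_type == "outward"], 3)
  expect_equal(ab$flow[ab$move_type == "return"], 4)
  expect_equal(ab$flow[ab$move_type == "transit"], 0)
})

test_that("move types partition each corridor's flow exactly", {
  for (seed in 1:5) {
    p <- random_closed_pair(5, seed + 100)
    arr <- pseudo_bayes(impute_min(p), impute_indep(p))
    fl <- flows_from_array(arr)
    mt <- move_type_decompose(arr)
    sums <- dplyr::summarise(dplyr::group_by(mt, orig, dest),
                             total = sum(flow), .groups = "drop")
    m <- merge(fl, sums, by = c("orig", "dest"))
    expect_equal(m$flow, m$total, tolerance = 1e-6)
  }
})

test_that("closed-system flows reproduce derived net migration per country", {
  w <- tiny_world(n_countries = 8, n_periods = 2, seed = 55)
  res <- estimate_all(w$stocks, w$demo,
                      methods = c("da_min_closed", "da_pb_closed"))
  demo_d <- derive_net_migration(w$demo)
  for (m in c("da_min_closed", "da_pb_closed")) {
    nf <- implied_net_flows(res$flows, m)
    cmp <- merge(nf, demo_d[, c("sex", "period_start", "country",
                                "net_migration")])
    expect_lt(max(abs(cmp$net_flow - cmp$net_migration)), 1e-3)
  }
})

test_that("flows from a pseudo-Bayes array are the weighted method flows", {
  p <- random_closed_pair(4, 31)
  arr_min <- impute_min(p)
  arr_indep <- impute_indep(p)
  fl_pb <- flows_from_array(pseudo_bayes(arr_min, arr_indep))
  fl_w <- 0.87 * flows_from_array(arr_min)$flow +
    0.13 * flows_from_array(arr_indep)$flow
  expect_equal(fl_pb$flow, fl_w, tolerance = 1e-12)
})
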
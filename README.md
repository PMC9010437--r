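# stockflows

Sex-specific bilateral international migration **flows** are missing for most
of the world: what countries report, through censuses and registers, are
bilateral migrant **stocks** — counts of people by country of birth and country
of residence at a point in time. `stockflows` converts sex-specific bilateral
stock tables on a five-year grid, together with demographic components
(populations, deaths, births and the sex ratio at birth), into estimates of
five-year origin–destination migration flows for each sex, using six
estimation methods, and provides the validation machinery to compare those
estimates against reported flow statistics. It is aimed at demographers and
migration researchers who work with UN-DESA-style stock tables and WPP-style
demographic components.

## Methods

Writing `s_ij^t` for the stock of people born in country *i* residing in
country *j* at time *t*, the six methods are:

* **`sd_drop_neg`** — stock differencing, negatives dropped:
  `y_ij = max(s_ij^{t+1} − s_ij^t, 0)`.
* **`sd_rev_neg`** — stock differencing, negatives reversed: a negative
  difference in corridor *j → i* is counted as a return flow
  `y_ij = max(d_ij, 0) + max(−d_ji, 0)`.
* **`mig_rate`** — rates-based allocation: the global flow total
  `G = Σ_k |net migration_k|` (from the demographic accounting equation) is
  distributed over corridors proportionally to start-of-period stocks,
  `y_ij = s_ij^t / Σ_hk s_hk^t · G`.
* **`da_min_open`**, **`da_min_closed`**, **`da_pb_closed`** — demographic
  accounting: deaths are subtracted from start-of-period stocks (allocated
  proportionally over birthplace within residence) and sex-specific births
  from the end-of-period home cells; per birthplace *k*, the adjusted start
  stocks give origin margins `y_i+k` and the adjusted end stocks destination
  margins `y_+jk` of a flow array `y_ijk`. Margin imbalances are either
  absorbed by an extra outside origin/destination (*open* system) or removed
  by scaling both tables to the mid-point of their totals (*closed* system).
  The diagonal stayer cells `y_iik` are set to their maximum feasible value
  `min(y_i+k, y_+ik)` and off-diagonal cells are imputed by iterative
  proportional fitting of a quasi-independent log-linear model; the
  pseudo-Bayesian variant combines this minimisation imputation with an
  independent (outer-product) imputation using a 0.87/0.13 weighting. Flows
  are the birthplace sums `y_ij = Σ_k y_ijk`, and the array also yields the
  decomposition into **outward** (`k = i`), **return** (`k = j`) and
  **transit** (other `k`) moves.

The closed-system estimates are constrained so that each country's inflows
minus outflows equal its net migration from the accounting equation
`pop_end = pop_start + births − deaths + net`.

## Worked example

Estimate flows for a small synthetic world with known demography:

```r
library(stockflows)
w <- generate_world(world_config(n_countries = 4, n_periods = 1, seed = 1))
res <- estimate_all(w$stocks, w$demo)
head(res$flows[res$flows$orig != res$flows$dest, ], 3)
#>      sex orig dest period_start sd_drop_neg sd_rev_neg mig_rate da_min_open da_min_closed da_pb_closed
#> 1 female C001 C002         1990     2007.32    2007.32 11468.48     4878.67       4878.67      12398.3
#> 2 female C001 C003         1990    14466.12   14466.12  6962.01    16015.77      16015.77      18952.0
#> 3 female C001 C004         1990     7862.84    7862.84 14192.12    11481.64      11481.64      17555.7
```

Each row is one origin–destination corridor for one sex and period, with one
estimated five-year flow (persons) per method. Summaries give totals, crude
migration rates (per thousand of start-of-period population per five-year
period) and sex shares:

```r
s <- summarise_flows(res$flows, w$demo)
s[s$method == "da_pb_closed", c("sex", "total", "crude_rate", "sex_share")]
#>      sex  total crude_rate sex_share
#> 1 female 283240      28.38    0.4647
#> 2   male 326322      29.60    0.5353
```

A two-country fixture reproduces a documented corner case of stock
differencing: between 2010 and 2015 the total Puerto-Rican-born stock in the
USA fell by 15,028 (so the total-stock method estimates a zero flow), yet the
female stock fell by 119,357 while the male stock rose by 104,329 — the
sex-specific method recovers a male flow the aggregate hides:

```r
fx <- puerto_rico_fixture()
drop_negative(difference_stocks(fx$stocks, 2010L))
#>      sex orig dest period_start sd_drop_neg
#> 1 female  PRI  USA         2010           0
#> 2 female  USA  PRI         2010           0
#> 3   male  PRI  USA         2010      104329
#> 4   male  USA  PRI         2010           0
```

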
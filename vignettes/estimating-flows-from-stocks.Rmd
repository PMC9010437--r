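---
title: "Estimating sex-specific migration flows from migrant stocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sex-specific migration flows from migrant stocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stockflows)
```

## The problem

Bilateral migrant *stocks* — people counted by country of birth and country of
residence at mid-year time points on a five-year grid — are available with
near-global coverage by sex. Bilateral migration *flows* — people changing
country of residence between two time points — are reported by only a few
dozen countries, with incompatible definitions. `stockflows` estimates
five-year flows from changes in stocks. All estimates are *transitions*: a
person counted in corridor $i \to j$ resided in $i$ at time $t$ and in $j$ at
time $t+5$. Moves within the interval (onward or back-and-forth migration,
moves by people who die before the period ends) are invisible by
construction, which is the main conceptual difference from event-based flow
statistics.

## The six estimators

Let $s_{ij}^t$ be the stock born in $i$ residing in $j$ at time $t$, and
$d_{ij} = s_{ij}^{t+1} - s_{ij}^t$.

**Stock differencing.** `drop_negative()` sets
$y_{ij} = \max(d_{ij}, 0)$; `reverse_negative()` additionally counts a
negative difference in the opposite corridor as a return flow,
$y_{ij} = \max(d_{ij}, 0) + \max(-d_{ji}, 0)$. When $d_{ij} > 0$ and
$d_{ji} < 0$ simultaneously, the two contributions are summed rather than
netted: both stocks can change for genuinely distinct groups of movers, and
netting would destroy the conservation identity
$\sum y = \sum |d|$ that makes the method auditable.

**Migration rates.** `global_flow_total()` approximates the global number of
migrants in a period by $G = \sum_k |\mathrm{net}_k|$, with net migration
derived per sex from the accounting equation; `rate_allocate()` distributes
$G$ proportionally to start-of-period stocks. The sum of absolute nets
double-counts in the sense that one migrant raises one country's net and
lowers another's; the formula is nevertheless applied as defined, and a
`halve_total` flag (default off) exposes the alternative.

**Demographic accounting.** `adjust_stocks()` removes period deaths from the
start-of-period table — allocated proportionally over birthplace within each
residence, i.e. mortality is assumed birthplace-neutral — and removes
sex-specific births from the end-of-period home cells, since children born
during the period cannot have migrated before it began. Per birthplace $k$,
the adjusted start stocks give the origin margins and the adjusted end stocks
the destination margins of the flow array $y_{ijk}$. `balance_open()` absorbs
per-birthplace margin imbalances in an extra outside origin or destination
(the OUT index; the OUT × OUT cell is structurally zero, since people never
observed in the bilateral table cannot be assigned a stay); `balance_closed()`
instead rescales both margin vectors to the mid-point of their totals, which
forces each country's estimated inflows minus outflows to equal its derived
net migration — the property the package's acceptance tests verify to
$10^{-9}$ on synthetic worlds.

`impute_min()` fixes the diagonal stayer cells at their per-index maximum
$y_{iik} = \min(\text{row}_i, \text{col}_i)$ and fits the off-diagonal cells
by iterative proportional fitting (IPF) of a quasi-independent log-linear
model: a flat seed of 1 in permitted cells, diagonal held at zero, scaled to
the residual margins. The per-index minimum is always jointly feasible:
after subtracting it, every index has a zero residual row or a zero residual
column, so the active rows and active columns are disjoint sets and the
residual problem is an ordinary (complete-bipartite) transportation problem
with equal totals. The same argument shows the stage-2 fit has the closed
form $r_i c_j / \sum r$ on the active rectangle, which the test suite uses as
an independent oracle against the IPF implementation. `impute_indep()` is the
independence fit $y_{ijk} = \text{row}_i \text{col}_j / \sum \text{row}$,
diagonal included; `pseudo_bayes()` combines the two imputations cell-wise
with weight $w_1 = 0.87$ on the minimisation fit. Because the diagonal
maximum minimises total migration given the margins, the pseudo-Bayesian
total can never fall below the minimisation total — a monotonicity the tests
check across many simulated worlds.

`move_type_decompose()` splits each corridor's flow by birthplace into
outward ($k = i$), return ($k = j$) and transit moves; the three parts
partition the flow exactly.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `w1` | 0.87 | pseudo-Bayesian weight on the minimisation imputation; a config constant, not re-estimated |
| `tol` | 1e-6 persons | IPF convergence: largest absolute margin deviation |
| `max_iter` | 1000 | IPF sweeps before a non-convergence error |
| `halve_total` | FALSE | divide the sum of absolute nets by two in the rates method |
| `log_zero` | "drop" | zero handling in the log-count validation measure |
| `layout` | "grid" | output rows: full origin × destination grid (diagonal zero) or corridors only |

Clamping order is fixed: adjust (deaths, births), then balance, then impute;
every clamp warns with the cell identity, so a clean run is silent.
Two-decimal rounding of the non-integer methods happens only in
`write_flow_estimates()`, never inside the pipeline.

## Conventions and open choices

* The sex ratio at birth is **male births per female birth** (the WPP
  convention): $\text{male} = B \cdot \text{srb}/(1+\text{srb})$.
  Sex-specific births are kept as reals, not rounded.
* Corridors absent from an input stock table are treated as zero stocks
  (dense completion over the harmonised country set).
* Country codes are opaque 3-letter strings; no ISO validation, because real
  study lists include non-ISO entities.
* Periods are labelled by their start year; a period spans $[t, t+5)$;
  annual reported flows in calendar years $t..t+4$ map to the period
  starting $t$.
* `five_year_equivalent()` multiplies the mean of the *available* annual
  flows by five, so partially observed periods are used rather than dropped.
* The log-count validation measure drops pairs containing a zero by default
  (`log_zero = "add1"` is available); percentiles in
  `discrepancy_summary()` use linear interpolation between order statistics
  (type 7).
* Harmonisation drops, with a warning, any country whose bilateral stocks
  are all zero at a time point: several estimators are undefined for such
  countries (zero allocation denominators, unscalable margins).
* Negative derived home stocks (population smaller than foreign-born
  residents) clamp to zero with a warning instead of aborting, so one
  inconsistent country does not kill a batch run.

## The synthetic world generator

`generate_world()` produces inputs with a known ground truth. True corridor
flows are sampled *first* (log-normal gravity-like weights scaled by an
out-migration intensity) and stocks are propagated from them, so
parameter-recovery tests are unambiguous. Within each period: deaths are
removed proportionally across birthplace within residence, survivors move
according to the sampled flows carrying their residence's birthplace
composition, and sex-specific births are added to the home cells. Populations
therefore satisfy the accounting equation exactly, and the generator's death
allocation matches the estimator's assumption, so closed-accounting recovery
is clean by design.

Defaults describe a small plausible world: per-sex country populations
uniform on 0.5–5 million, five-year birth rate 0.10 and death rate 0.07 (per
person of start population, bracketing crude world vital rates over five
years), out-migration intensity 0.02 per five years, initial diaspora share
0.05, and SRB uniform on 1.04–1.07. One RNG stream per (sex, period) is
derived from the master seed, so identical seeds give identical worlds.

What the generator does *not* emulate: measurement error and revisions in
stock data, refugee adjustments, citizenship-as-birthplace proxying,
countries appearing or splitting between periods, and birthplace-selective
mortality (an assumption the estimator shares — because generator and
estimator agree here, passing recovery tests demonstrate internal
consistency, not robustness of the mortality assumption on real data).

## Problem sizes and numerical checks

The shipped tests run synthetic worlds of 3–20 countries over 1–3 periods
(the closed-system net-migration check uses 20 countries × 3 periods;
monotonicity uses 50 seeds of 6-country worlds; imputation oracles use 100
random 3×3 and 4×4 margin sets), sizes at which every estimator's structural
identities — conservation, margin reproduction, partitions, net constraints —
are exact up to the stated tolerances. The method scales as
$O(n^3)$ per sex-period through the $n \times n \times n$ array; a 200-country
period is routine.

## Limitations

Transitions under-count events over five years; estimates inherit all error
in the input stocks and demographic components; the 0.87 weight stems from
comparisons dominated by intra-European flows and may push global totals
toward the upper end of a feasible range; and the stock-differencing methods
ignore demography entirely, so they confound mortality-driven stock decline
with return migration. Users should prefer the method whose validation
correlations are strongest for their measure of interest and cross-check with
a second method.
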
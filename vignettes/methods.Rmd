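---
title: "Methods: cohort-component projection and the demographic dividend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-component projection and the demographic dividend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dividendsim)
```

## The model and its assumptions

`dividendsim` projects a closed or nearly closed population forward one
calendar year at a time on single ages 0–80+ by sex, using the standard
cohort-component decomposition: survival moves each cohort up one age,
fertility generates an interval birth cohort, the sex ratio at birth
splits it, and infant survival carries it to its first mid-year. All
stocks are mid-year populations; all flows are mid-year-to-mid-year
intervals. The accounting identity

> total(t) − total(t−1) = births − deaths + net migration

holds to machine precision for every projected interval and is asserted
by the test suite.

The interval bookkeeping averages both endpoints symmetrically: the
survival applied to a cohort over (t−1, t] is the mean of the survival
ratios of the life tables in force at t−1 and t; births average the
female population, the TFR, and the fertility age distribution at the two
bounding mid-years; migrants are credited half to each bounding year.
Deaths are defined as the entering cohort (including its half-interval
migrants) times one minus the mean survival ratio — the one formulation
that keeps the accounting identity exact and dimensions consistent. The
age-0 population is the interval's births of each sex times the
birth-to-mid-year survival factor `L0/l0` (mean of the two bounding
years' life tables); defining it this way, rather than through any
self-referential expression, is the only non-circular closure of the
annual loop.

Fertility is parameterized as a total fertility rate plus a *normalized*
age distribution of fertility `f(a, t)` on ages 15–49 with
`sum_a f(a, t) = 1` each year. This makes the TFR interpretation exact —
inverting the births formula on a noiseless projection recovers the input
TFR to 10⁻⁶, which the suite checks — and lets five-year ASFR inputs be
adapted by uniform spreading within groups.

## Mortality: the relational life-table fit

A goalpost-style projection needs a full survival schedule from a single
life-expectancy input. The package uses a Brass logit relational model:
with `l(x)` the probability of surviving to exact age x and
`Y(x) = ½·log((1−l)/l)` its logit, the fitted schedule is
`Y(x) = α + Y_std(x)` with slope fixed at 1, and α is solved by
`uniroot` (tolerance 10⁻¹² on α, giving e₀ agreement well below the
documented 0.05-year bound) so the fitted table hits the target e₀.

The bundled standard is generated in code from a Siler hazard
(exponentially declining infant component + constant background +
Gompertz senescence), with sex-specific parameters giving e₀ ≈ 68
(female) and ≈ 64 (male) — an early-2000s South-Asia-like shape. It is a
synthetic standard, labelled as such in its provenance string, not an
empirical model life table; the relational fit makes results insensitive
to the standard's exact level, and any user-supplied `lx` column can be
used instead via `life_table_from_lx()` / the `standard` argument of
`fit_life_table()`.

Numerical conventions: the internal survivorship column extends to age
130 so the open 80+ group's person-years are accumulated explicitly;
person-years use a separation factor of 0.3 in the first year of life
(infant deaths cluster early in the interval) and 0.5 at all later ages;
the attainable e₀ interval under the default α bounds (±3.5) is roughly
1–100 years and out-of-range targets fail with the achievable interval in
the message. The terminal survival ratio is the person-years aggregate
ratio `T(80)/T(79)` applied to the pooled ages 79 and 80+ cohort.

## Age disaggregation: Beers ordinary

Five-year inputs are split to single ages with the published Beers
"ordinary" multipliers — the classical default for census disaggregation
(the "modified" variant smooths across group boundaries and is not
offered). The coefficient panels preserve each group's total exactly,
which the suite asserts on randomized inputs and against an independent
matrix-operator oracle. The polynomial panels can return small negative
single-age values on sharply irregular inputs; these are floored at zero
with the group's mass redistributed proportionally (group sum preserved)
and a warning raised. At least 5 consecutive groups are required — the
minimum the panel scheme (two boundary panels each side plus interior
panels) supports.

## Scenarios and interpolation

A scenario is a named bundle of annual series built from sparse
`(year, value)` goalpost anchors: TFR, fertility-distribution mode and
spread, SRB, e₀ by sex, GDP growth, labour-force participation (15–64 and
10–14 by sex), and the education/health/urbanization service ratios.
Interpolation between anchors is linear with constant extension outside
the anchor range: goalposts state endpoints, and a linear path is the
minimal assumption; the `interpolation` field is kept in the spec so
alternative rules can be added without changing the file format. Anchor
lists — not derived series — are what serialize to YAML, so round-trips
are lossless and deterministic.

The two bundled builders differ only in demography: `build_as_usual()`
freezes TFR, fertility distribution, SRB and e₀ at base-year values while
socio-economic goalposts still progress; `build_emphasis()` moves the
demographic inputs too (TFR 3.14 → 2.1 in 2020 → 1.74 by 2060, SRB
111 → 108, e₀ rising to 78/75 f/m). Both share one exogenous GDP-growth
path by default, so scenario differences in GDP per capita are driven by
demography alone — precisely the quantity the dividend isolates. Net
migration defaults to zero in both (a user-supplied age-sex-year schedule
is accepted); at the horizon in question migration is a second-order
effect and a zero default keeps the scenario contrast clean.

The fertility age distribution is a discretized normal on 15–49
(renormalized), parameterized by its mode age and spread. Under the
emphasis path the mode moves from 25 to 29 and the spread narrows
slightly, shifting mass out of ages 15–19 monotonically over the horizon
— the adolescent-fertility decline that accompanies family-planning
progress.

## Base-year defaults

Values a configuration must state but that no single authoritative source
pins down were chosen once as India-like circa 2001 and fixed: e₀ 63.9
(f) / 62.3 (m); LFPR 15–64 0.80 (m) / 0.30 (f) and 10–14 0.05 (both),
moving to 0.86 / 0.65 / 0.001 by 2061; annual GDP growth 0.07 at 2001
declining linearly to 0.02 at 2061; student–teacher ratio 40 → 13;
population per doctor 1700 → 300; urban share 0.28 → 0.70; persons per
urban household 5 → 2; gross enrolment ratio 0.8 → 1.0. Base GDP is set
so base-year GDP per capita equals 42.55 thousand rupees, putting
per-capita outputs on a thousand-rupee scale.

## The synthetic-data generator

`make_base_population()` draws its age shape from stable-population
theory: `c(a) ∝ exp(−r·a)·L(a)` per sex, scaled to the configured total,
with the intrinsic rate r either supplied or solved from the discrete
Euler–Lotka equation for the configured fertility and mortality (so the
default pyramid is self-consistent with TFR 3.14). Optional multiplicative
lognormal noise (mean-one, configured relative s.d.) applies to counts
only — never to rate schedules, so vital rates remain exactly recoverable
in parameter-recovery tests. All randomness flows from one explicit seed
through `withr::with_seed`; no global RNG state leaks.

What the generator emulates: a young, high-fertility, two-sex pyramid
with SRB-consistent sex composition and the goalpost anchor bundles of
the two study scenarios. What it does not emulate: cohort irregularities
of a real census (age heaping, enumeration error, migration scars,
momentum from *past* fertility decline — a stable pyramid is smoother and
somewhat older than an actual 2001 high-fertility population, which is
why the default bundle's window of opportunity opens at the base year
rather than a decade in). Passing tests therefore demonstrate the
*mechanics* — accounting exactness, oracle equivalence, stationarity,
rate recovery — not calibration to any historical population; projecting
a real census pyramid requires supplying it via `read_age_sex_csv()`.

## Indicators and the window of opportunity

Dependency ratios use the standard bands: child 0–14 and old-age 65+ per
100 persons 15–64, with the total the exact sum of the two. The UN
window opens in the first year with the under-15 share below 30 % and
the 65+ share below 15 %, and closes with the last consecutive such
year; the *effective* window keeps the same opening but closes at the
total dependency ratio's minimum — the point after which population
ageing pushes the overall burden back up — with argmin ties broken toward
the earliest year. "Never attained" is a valid report, not an error.

GDP compounds recursively at the exogenous growth series; per-capita
values divide by total population; the dividend is the elementwise
per-capita difference (emphasis − as-usual), zero at the shared base year
by construction, and antisymmetric under scenario exchange.

## Problem sizes and tolerances in the test suite

The suite runs two full 61-year projections (≈ 1 s), one 200-year
stationarity run (NRR = 1, SRB 100, fixed mortality; final annual change
below 0.1 % and sup-norm distance to the `Lx`-proportional stationary
structure below 0.5 %), a 31-year stable-growth run (realized growth
within 0.002/yr of the Euler–Lotka rate), life-table fits across targets
40–85 (error < 0.05 years each), and randomized property checks at 10–20
replicates per property. Oracle comparisons (Leslie matrix, Beers
operator, trapezoidal e₀, exhaustive window scan, closed-form compound
growth) use tolerances of 10⁻⁹–10⁻¹² as documented in each test; these
sizes keep the whole suite around ten seconds while leaving every
asymptotic check (stationarity, stable growth) already deep in its
converged regime.

## Known limitations

- No second demographic dividend: life-cycle savings and capital
  deepening are outside the model; the dividend here is purely the
  per-capita accounting effect of slower population growth under a shared
  GDP path.
- GDP is exogenous: labour-force size, education and health indicators
  are computed as requirements/supplies but do not feed back into growth.
- Single-region, annual-step, deterministic: no sub-annual dynamics, no
  stochastic variants, no inter-regional flows.
- The open age group at 80+ pools everyone above; analyses of the
  oldest-old need a higher terminal age and a standard schedule to match.
- Urbanization/agriculture are represented only through the service-ratio
  goalposts (dwellings), not through land or crop balances.
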
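# The cohort-component engine: births, sex split, cohort advancement,
# infant survival, and the assembled annual projection.

test_that("births vanish without fertility and scale linearly in women", {
  fp <- stats::setNames(rep(1000, 81), 0:80)
  d <- stats::setNames(rep(1 / 35, 35), 15:49)
  expect_equal(compute_births(fp, fp, 0, 0, d, d), 0)
  b1 <- compute_births(fp, fp, 2, 2, d, d)
  b2 <- compute_births(2 * fp, 2 * fp, 2, 2, d, d)
  expect_equal(b2, 2 * b1, tolerance = 1e-12)
})

test_that("a single fertile age matches the direct-formula oracle", {
  fp <- stats::setNames(rep(0, 81), 0:80)
  fp["25"] <- 1000
  d <- stats::setNames(c(1), 25)
  got <- compute_births(fp, fp, 2, 2, d, d)
  # direct evaluation: mean(fp) * mean(tfr) * mean(dist) at the one age
  expect_equal(got, 1000 * 2 * 1, tolerance = 1e-9)
  # interval averaging of both endpoints
  fp2 <- fp; fp2["25"] <- 3000
  expect_equal(compute_births(fp, fp2, 1, 3, d, d),
               0.5 * (1000 + 3000) * 0.5 * (1 + 3), tolerance = 1e-9)
})

test_that("births validate distribution support and TFR sign", {
  fp <- stats::setNames(rep(1000, 81), 0:80)
  bad <- stats::setNames(c(0.5, 0.5), c(14, 30))
  ok <- stats::setNames(c(1), 30)
  expect_error(compute_births(fp, fp, 2, 2, bad, bad), "15-49")
  expect_error(compute_births(fp, fp, -1, 2, ok, ok), "non-negative")
})

test_that("sex split follows the SRB and conserves births", {
  s <- split_births_by_sex(2110, srb = 111)
  expect_equal(unname(s["male"]), 1110, tolerance = 1e-9)
  expect_equal(unname(s["female"]), 1000, tolerance = 1e-9)
  s2 <- split_births_by_sex(500, srb = 100)
  expect_equal(unname(s2["male"]), unname(s2["female"]))
  set.seed(8)
  for (srb in stats::runif(5, 80, 130)) {
    b <- stats::runif(1, 0, 1e6)
    expect_equal(sum(split_births_by_sex(b, srb)), b, tolerance = 1e-9)
  }
  expect_error(split_births_by_sex(100, srb = 0), "positive")
})

test_that("advance_cohorts matches the Leslie single-step oracle on the toy", {
  pop <- c(100, 50, 20)
  s <- c(0.9, 0.5)   # into age 1; terminal pooled ratio
  adv <- advance_cohorts(pop, s, s)
  oracle <- leslie_matrix(s) %*% pop
  expect_equal(unname(adv$pop[2:3]), oracle[2:3], tolerance = 1e-9)
  expect_equal(unname(adv$deaths[2]), 100 * 0.1, tolerance = 1e-9)
  expect_equal(unname(adv$deaths[3]), (50 + 20) * 0.5, tolerance = 1e-9)
})

test_that("a 3-year survival-only projection equals the Leslie cube", {
  pop0 <- c(120, 100, 80, 60, 40)
  s <- c(0.95, 0.9, 0.85, 0.6)
  M <- leslie_matrix(s)
  pop <- pop0
  for (k in 1:3) {
    adv <- advance_cohorts(pop, s, s)
    pop <- adv$pop
    pop[1] <- unname(infant_population(c(female = 0, male = 0),
                                       c(female = 1, male = 1))["female"])
  }
  oracle <- M %*% M %*% M %*% pop0
  expect_equal(unname(pop), as.vector(oracle), tolerance = 1e-9)
})

test_that("unit survival shifts cohorts without deaths; empty stays empty", {
  pop <- c(5, 4, 3, 2, 1)
  ones <- rep(1, 4)
  adv <- advance_cohorts(pop, ones, ones)
  expect_equal(unname(adv$pop[2:5]), c(5, 4, 3, 2 + 1))
  expect_equal(sum(adv$deaths), 0)
  advz <- advance_cohorts(rep(0, 5), ones * 0.5, ones * 0.5)
  expect_equal(sum(advz$pop[-1]), 0)
  expect_equal(sum(advz$deaths), 0)
})

test_that("interval migration enters with half weight on each side", {
  pop <- c(100, 100, 100)
  s <- c(0.8, 0.5)
  mig_prev <- c(10, 0, 0)    # migrants at age 0 in the earlier year
  mig_curr <- c(0, 6, 0)     # migrants at age 1 in the later year
  adv <- advance_cohorts(pop, s, s, mig_prev, mig_curr)
  expect_equal(unname(adv$pop[2]), (100 + 0.5 * (10 + 6)) * 0.8,
               tolerance = 1e-12)
})

test_that("infant cohort survives by the life-table factor", {
  b <- c(female = 480, male = 520)
  out <- infant_population(b, c(female = 0.96, male = 0.95))
  expect_equal(unname(out["female"]), 480 * 0.96, tolerance = 1e-12)
  expect_equal(unname(attr(out, "deaths")["male"]), 520 * 0.05,
               tolerance = 1e-12)
  expect_equal(unname(infant_population(b, c(female = 1, male = 1))),
               unname(b), ignore_attr = TRUE)
  zero <- infant_population(c(female = 0, male = 0),
                            c(female = 0.9, male = 0.9))
  expect_equal(unname(zero), c(0, 0), ignore_attr = TRUE)
  expect_error(infant_population(b, c(female = 1.2, male = 0.9)), "0, 1")
})

test_that("horizon 0 returns exactly the base table", {
  sc <- const_scenario()
  base <- age_sex_table(2001, rep(100, 81), rep(100, 81))
  res <- project(sc, base, horizon = 0)
  expect_equal(dim(res$pop)[3], 1L)
  expect_equal(unname(res$pop[, "female", 1]), rep(100, 81))
  expect_equal(nrow(res$vital), 0L)
})

test_that("demographic accounting balances every interval", {
  sc <- const_scenario(end = 2021)
  base <- make_base_population(synthetic_config(seed = 9, noise = 0.05))
  res <- project(sc, base)
  tot <- projected_totals(res)
  v <- res$vital
  lhs <- diff(tot)
  rhs <- v$births_f + v$births_m - v$deaths_total + v$net_migration
  expect_equal(lhs, rhs, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("accounting balances under a non-zero migration schedule", {
  sc <- const_scenario(end = 2011)
  base <- age_sex_table(2001, rep(1000, 81), rep(1000, 81))
  mig <- zero_migration(2001:2011)
  set.seed(21)
  mig$net[, , ] <- stats::rnorm(length(mig$net), mean = 2, sd = 1)
  res <- project(sc, base, migration = mig)
  tot <- projected_totals(res)
  v <- res$vital
  expect_equal(diff(tot),
               v$births_f + v$births_m - v$deaths_total + v$net_migration,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("projection is deterministic and monotone in fertility", {
  base <- make_base_population(synthetic_config(seed = 13))
  sc <- const_scenario(end = 2021)
  r1 <- project(sc, base)
  r2 <- project(sc, base)
  expect_identical(r1, r2)
  sc_hi <- const_scenario(tfr = 3.5, end = 2021)
  r_hi <- project(sc_hi, base)
  expect_true(all(projected_totals(r_hi) >= projected_totals(r1) - 1e-9))
})

test_that("replacement-level inputs converge to the stationary structure", {
  # NRR = 1: TFR tuned from the same female schedule the engine uses
  lt_f <- fit_life_table(63.9, "female")
  d <- make_fertility_schedule(synthetic_config())$dist[, 1]
  Lx <- lt_f$Lx[match(15:49, lt_f$age)] / lt_f$lx[1]
  tfr_repl <- 1 / (0.5 * sum(d * Lx))
  inputs <- default_inputs(2001, 2201)
  inputs$base <- list(tfr = tfr_repl, srb = 100, e0_f = 63.9, e0_m = 63.9,
                      dist_mode = 25, dist_spread = 5.5)
  sc <- build_as_usual(inputs)
  base <- age_sex_table(2001, rep(1000, 81), rep(1000, 81))
  res <- project(sc, base)
  tot <- projected_totals(res)
  n <- length(tot)
  expect_lt(abs(tot[n] / tot[n - 1] - 1), 0.001)   # < 0.1 % per year
  for (sx in c("female", "male")) {
    stat <- fit_life_table(63.9, sx)$Lx
    stat <- stat / sum(stat)
    obs <- res$pop[, sx, n] / sum(res$pop[, sx, n])
    expect_lt(max(abs(obs - stat)), 0.005)          # sup norm < 0.5 %
  }
})

test_that("projection failures identify the offending year", {
  inputs <- default_inputs(2001, 2011)
  inputs$base <- list(tfr = 3, srb = 111, e0_f = 63.9, e0_m = 62.3,
                      dist_mode = 25, dist_spread = 5.5)
  sc <- build_as_usual(inputs)
  sc$series$e0_f["2006"] <- 150   # unattainable mid-horizon
  base <- age_sex_table(2001, rep(1000, 81), rep(1000, 81))
  expect_error(project(sc, base), "year 2006")
})

test_that("projection CSV export round-trips populations", {
  sc <- const_scenario(end = 2006)
  base <- age_sex_table(2001, rep(1000, 81), rep(900, 81))
  res <- project(sc, base)
  pop_path <- withr::local_tempfile(fileext = ".csv")
  vit_path <- withr::local_tempfile(fileext = ".csv")
  write_projection_csv(res, pop_path, vit_path)
  pop <- utils::read.csv(pop_path)
  expect_equal(nrow(pop), 81 * 2 * 6)
  y5 <- pop[pop$year == 2006 & pop$sex == "female", ]
  expect_equal(y5$population[order(y5$age)],
               unname(res$pop[, "female", 6]), tolerance = 1e-12)
  vit <- utils::read.csv(vit_path)
  expect_equal(vit$births_f, res$vital$births_f, tolerance = 1e-12)
})
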
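# Dependency ratios, window detection, GDP, per-capita series, dividend,
# labour force and service requirements.

# small helper: a projection_result-like object with prescribed band masses
fake_result <- function(child, working, old, years = seq_along(child)) {
  n <- length(years)
  child <- rep(child, length.out = n)
  working <- rep(working, length.out = n)
  old <- rep(old, length.out = n)
  pop <- array(0, dim = c(81, 2, n),
               dimnames = list(age = 0:80, sex = c("female", "male"),
                               year = years))
  for (i in seq_len(n)) {
    pop["5", "female", i] <- child[i]
    pop["30", "female", i] <- working[i]
    pop["70", "female", i] <- old[i]
  }
  structure(list(scenario_id = "fake", years = as.integer(years), pop = pop,
                 vital = data.frame()),
            class = "projection_result")
}

test_that("dependency ratios follow the band arithmetic", {
  res <- fake_result(30, 60, 10)
  d <- dependency_ratios(res)
  expect_equal(d$dep_child, 50)
  expect_equal(d$dep_old, 100 * 10 / 60, tolerance = 1e-9)
  expect_equal(d$dep_total, d$dep_child + d$dep_old, tolerance = 1e-9)
  all_working <- fake_result(0, 100, 0)
  expect_equal(dependency_ratios(all_working)$dep_total, 0)
  expect_error(dependency_ratios(fake_result(10, 0, 5)), "working-age")
})

test_that("child + old = total on random band tables", {
  set.seed(23)
  res <- fake_result(stats::runif(10, 10, 50), stats::runif(10, 40, 80),
                     stats::runif(10, 5, 30))
  d <- dependency_ratios(res)
  expect_equal(d$dep_total, d$dep_child + d$dep_old, tolerance = 1e-9)
  s <- population_shares(res)
  expect_equal(s$share_0_14 + s$share_15_64 + s$share_65p, rep(1, 10),
               tolerance = 1e-12)
})

test_that("window detector reproduces a constructed 2011-2041 window", {
  years <- 2001:2061
  # under-15 share crosses 30 % between 2010 and 2011; old-age share low
  share_child <- seq(0.35, 0.20, length.out = 61)
  share_child[years <= 2010] <- 0.31
  share_child[years >= 2011] <- seq(0.299, 0.20,
                                    length.out = sum(years >= 2011))
  share_old <- seq(0.04, 0.14, length.out = 61)
  dep_total <- c(seq(80, 50, length.out = 41), seq(50.5, 70, length.out = 20))
  df <- data.frame(year = years, share_0_14 = share_child,
                   share_65p = share_old, dep_total = dep_total)
  w <- window_of_opportunity(df)
  expect_true(w$attained)
  expect_equal(w$effective_open_year, 2011)
  expect_equal(w$effective_close_year, 2041)  # dependency minimum
  expect_equal(w$un_open_year, 2011)
})

test_that("window not attained when the child share never falls", {
  df <- data.frame(year = 2001:2020, share_0_14 = rep(0.40, 20),
                   share_65p = rep(0.05, 20), dep_total = seq(90, 70, -20 / 19))
  w <- window_of_opportunity(df)
  expect_false(w$attained)
  expect_true(is.na(w$un_open_year))
})

test_that("window detector agrees with the exhaustive scan on random series", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    years <- 2000 + seq_len(n)
    df <- data.frame(
      year = years,
      share_0_14 = stats::runif(n, 0.15, 0.45),
      share_65p = stats::runif(n, 0.02, 0.20),
      dep_total = stats::runif(n, 40, 100))
    w <- window_of_opportunity(df)
    o <- window_scan(df$year, df$share_0_14, df$share_65p, df$dep_total)
    if (is.na(o$open)) {
      expect_false(w$attained)
    } else {
      expect_equal(w$un_open_year, o$open)
      expect_equal(w$effective_close_year, o$eff_close)
    }
  }
})

test_that("argmin ties break toward the earliest year", {
  df <- data.frame(year = 2001:2010,
                   share_0_14 = rep(0.2, 10), share_65p = rep(0.1, 10),
                   dep_total = c(60, 50, 50, 55, 50, 60, 70, 70, 70, 70))
  expect_equal(window_of_opportunity(df)$effective_close_year, 2002)
})

test_that("GDP compounds at the exogenous rate", {
  g0 <- stats::setNames(rep(0, 11), 2000:2010)
  expect_equal(unname(project_gdp(100, g0)), rep(100, 11))
  g2 <- stats::setNames(rep(0.02, 11), 2000:2010)
  gdp <- project_gdp(100, g2)
  expect_equal(unname(gdp["2010"]), 100 * 1.02^10, tolerance = 1e-12)
  expect_true(all(project_gdp(100, stats::setNames(rep(-0.5, 5), 1:5)) > 0))
  expect_error(project_gdp(100, c(0.02, -1)), "-1")
  expect_error(project_gdp(-5, g2), "positive")
  # step-wise identity: GDP(t) = GDP(t-1) * (1 + g)
  expect_equal(unname(gdp[-1] / gdp[-11]), rep(1.02, 10), tolerance = 1e-9)
})

test_that("per-capita series divide GDP by population", {
  gdp <- stats::setNames(c(100, 110, 121), 2001:2003)
  pop <- stats::setNames(c(1, 1, 1), 2001:2003)
  expect_equal(gdp_per_capita(gdp, pop), gdp)
  pop2 <- pop * 2
  expect_equal(unname(gdp_per_capita(gdp, pop2)), unname(gdp) / 2)
  expect_error(gdp_per_capita(gdp, stats::setNames(pop, 2002:2004)),
               "identical years")
})

test_that("dividend is the elementwise scenario difference", {
  em <- stats::setNames(c(42.55, 548.60), c(2001, 2061))
  au <- stats::setNames(c(42.55, 382.75), c(2001, 2061))
  d <- dividend(em, au)
  expect_equal(d$dividend, c(0, 165.85), tolerance = 1e-9)
  expect_equal(dividend(au, au)$dividend, c(0, 0))
  # antisymmetry
  expect_equal(dividend(em, au)$dividend, -dividend(au, em)$dividend)
})

test_that("a uniformly smaller population yields a positive dividend", {
  yrs <- as.character(2001:2011)
  gdp <- project_gdp(1000, stats::setNames(rep(0.03, 11), yrs))
  big <- stats::setNames(seq(100, 120, 2), yrs)
  small <- big * stats::setNames(c(1, rep(0.95, 10)), yrs)
  d <- dividend(gdp_per_capita(gdp, small), gdp_per_capita(gdp, big))
  expect_true(all(d$dividend[-1] > 0))
  expect_equal(d$dividend[1], 0)
})

test_that("labour force applies band participation rates", {
  sc <- build_emphasis(default_inputs())
  res <- fake_result(0, 100, 0, years = 2001:2061)
  # all mass at age 30, female: workers = 100 * lfpr_f_15_64
  lf <- labour_force(res, sc)
  expect_equal(lf$workers_f,
               unname(100 * sc$series$lfpr_f_15_64), tolerance = 1e-9)
  expect_equal(lf$workers_m, rep(0, 61))
  expect_true(all(lf$workers_total <= 100 + 1e-9))
  # linearity in population
  res2 <- fake_result(0, 200, 0, years = 2001:2061)
  expect_equal(labour_force(res2, sc)$workers_f, 2 * lf$workers_f,
               tolerance = 1e-9)
})

test_that("service requirements follow the goalpost ratios", {
  inputs <- default_inputs(2001, 2003)
  sc <- build_emphasis(inputs)
  sc$series$students_per_teacher[] <- 13
  sc$series$ger[] <- 1
  sc$series$pop_per_doctor[] <- 500
  sc$series$urban_share[] <- 0.7
  sc$series$persons_per_household[] <- 2
  n <- 3
  pop <- array(0, dim = c(81, 2, n),
               dimnames = list(age = 0:80, sex = c("female", "male"),
                               year = 2001:2003))
  pop["10", "female", ] <- 1300   # school-age
  pop["40", "male", ] <- 700
  res <- structure(list(scenario_id = "x", years = 2001:2003, pop = pop,
                        vital = data.frame()),
                   class = "projection_result")
  req <- service_requirements(res, sc)
  expect_equal(req$teachers, rep(1300 / 13, n), tolerance = 1e-9)   # 100
  expect_equal(req$doctors, rep(2000 / 500, n), tolerance = 1e-9)
  expect_equal(req$urban_dwellings, rep(2000 * 0.7 / 2, n),
               tolerance = 1e-9)                                    # 700
  # zero population, zero requirements
  res0 <- fake_result(0, 0, 0, years = 2001:2003)
  res0$pop["30", "female", ] <- 1  # keep working-age non-zero elsewhere
  req0 <- service_requirements(res0, sc)
  expect_equal(req0$teachers, rep(0, 3))
})

test_that("scenario_indicators assembles consistent columns", {
  sc <- const_scenario(end = 2011)
  base <- make_base_population(synthetic_config(seed = 4))
  res <- project(sc, base)
  ind <- scenario_indicators(res, sc, base_gdp = 1000)
  expect_equal(ind$dep_total, ind$dep_child + ind$dep_old, tolerance = 1e-9)
  expect_equal(ind$gdp_pc, ind$gdp / projected_totals(res),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ind$gdp[1], 1000)
})
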
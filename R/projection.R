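# The cohort-component engine: advance cohorts with interval survival and
# net migration, generate births from TFR and the age distribution of
# fertility, split births by the sex ratio at birth, and survive the birth
# cohort into age 0. One annual step runs mid-year to mid-year; the full
# projection iterates the step over the scenario horizon.

#' An all-zero net migration schedule
#'
#' @param years Calendar years covered.
#' @return A `migration_schedule`: list with `years` and a numeric array
#'   `net` of dim (ages, sexes, years), all zero.
#' @export
zero_migration <- function(years) {
  net <- array(0, dim = c(length(AGES), 2L, length(years)),
               dimnames = list(age = AGES, sex = SEXES, year = years))
  structure(list(years = as.integer(years), net = net),
            class = "migration_schedule")
}

.mig_slice <- function(mig, year, sex) {
  i <- match(year, mig$years)
  assert_that(!is.na(i), "migration schedule does not cover year %d", year)
  mig$net[, sex, i]
}

#' Births between two mid-years
#'
#' Interval births are the sum over reproductive ages 15-49 of the
#' mid-interval female population times the mid-interval TFR times the
#' mid-interval fraction of lifetime fertility at each age: each factor is
#' the average of its values at the bounding mid-years.
#'
#' @param fp_prev,fp_curr Female counts by single age 0..80+ (named by age)
#'   at the start and end mid-years.
#' @param tfr_prev,tfr_curr Total fertility rate at the bounding years,
#'   children per woman.
#' @param dist_prev,dist_curr Normalized age distribution of fertility over
#'   ages 15..49 (each sums to 1; zero mass outside 15-49).
#' @return Total births in the interval (persons, both sexes).
#' @export
#' @examples
#' fp <- setNames(rep(1000, 81), 0:80)
#' d <- setNames(rep(1 / 35, 35), 15:49)
#' compute_births(fp, fp, 2, 2, d, d)
compute_births <- function(fp_prev, fp_curr, tfr_prev, tfr_curr,
                           dist_prev, dist_curr) {
  assert_that(tfr_prev >= 0 && tfr_curr >= 0, "TFR must be non-negative")
  for (d in list(dist_prev, dist_curr)) {
    assert_that(all(d >= 0), "fertility distribution must be non-negative")
    ages_d <- as.integer(names(d))
    assert_that(!is.null(names(d)) && all(ages_d >= 15 & ages_d <= 49),
                "fertility distribution mass must lie within ages 15-49")
    assert_that(abs(sum(d) - 1) < 1e-6,
                "fertility distribution must sum to 1 (got %.8f)", sum(d))
  }
  fert_ages <- as.character(15:49)
  fp_mid <- 0.5 * (fp_prev[fert_ages] + fp_curr[fert_ages])
  tfr_mid <- 0.5 * (tfr_prev + tfr_curr)
  d_prev <- d_curr <- stats::setNames(numeric(35), fert_ages)
  d_prev[names(dist_prev)] <- dist_prev
  d_curr[names(dist_curr)] <- dist_curr
  dist_mid <- 0.5 * (d_prev + d_curr)
  sum(fp_mid * tfr_mid * dist_mid)
}

#' Split interval births by the sex ratio at birth
#'
#' @param births_total Total births, persons.
#' @param srb Sex ratio at birth, male births per 100 female births.
#' @return Named vector `c(male =, female =)`; the two components sum to
#'   `births_total`.
#' @export
#' @examples
#' split_births_by_sex(2110, srb = 111)  # 1110 boys, 1000 girls
split_births_by_sex <- function(births_total, srb) {
  assert_that(is.numeric(srb) && srb > 0, "`srb` must be positive")
  assert_that(births_total >= 0, "`births_total` must be non-negative")
  srb <- unname(srb)
  births_total <- unname(births_total)
  male <- births_total * srb / (100 + srb)
  c(male = male, female = births_total - male)
}

#' Advance all cohorts one year
#'
#' Implements the mid-year to mid-year bookkeeping for ages 1 and above:
#' the population reaching age `a` at time `t` is the age `a - 1` cohort at
#' `t - 1`, plus half the net migration attributed to each bounding year,
#' minus interval deaths. Deaths are the entering cohort (including the
#' half-interval migrants) times one minus the mean of the two bounding
#' years' survival ratios. Survivors of ages `A - 1` and `A`+ pool into the
#' open terminal group using the terminal person-years aggregate ratio.
#'
#' @param pop_prev Counts by single age `0..A` (A the open terminal age,
#'   80+ on the package's standard grid) for one sex at `t - 1`.
#' @param surv_prev,surv_curr `advance` vectors from [survival_ratios()] for
#'   the life tables in force at `t - 1` and `t` (entry `a` is the ratio for
#'   advancing into age `a`, length `A`; the last entry is the terminal
#'   aggregate ratio).
#' @param mig_prev,mig_curr Net migrant counts by age for this sex at
#'   `t - 1` and `t` (default zero).
#' @return A list with `pop` (counts at `t` for ages `1..A`, age 0 left
#'   `NA` for [infant_population()] to fill) and `deaths` (interval deaths
#'   by age at `t`, i.e. deaths of the cohort arriving at each age).
#' @export
advance_cohorts <- function(pop_prev, surv_prev, surv_curr,
                            mig_prev = NULL, mig_curr = NULL) {
  n <- length(pop_prev)
  A <- n - 1L
  assert_that(n >= 3, "`pop_prev` must cover at least ages 0..2")
  assert_that(length(surv_prev) == A && length(surv_curr) == A,
              "survival ratio vectors must have length %d (ages 1..%d)",
              A, A)
  assert_that(all(surv_prev > 0 & surv_prev <= 1) &&
              all(surv_curr > 0 & surv_curr <= 1),
              "survival ratios must lie in (0, 1]")
  if (is.null(mig_prev)) mig_prev <- numeric(n)
  if (is.null(mig_curr)) mig_curr <- numeric(n)

  s_mean <- 0.5 * (surv_prev + surv_curr)     # indexed by destination age 1..A
  pop <- stats::setNames(rep(NA_real_, n), 0:A)
  deaths <- stats::setNames(numeric(n), 0:A)

  # destination ages 1 .. A-1: cohort from age a-1 plus half-interval migration
  a <- 1:(A - 1)
  entering <- pop_prev[a] + 0.5 * (mig_prev[a] + mig_curr[a + 1])
  pop[a + 1] <- entering * s_mean[a]
  deaths[a + 1] <- entering * (1 - s_mean[a])

  # open terminal group pools survivors of ages A-1 and A+
  ent_term <- pop_prev[A] + pop_prev[A + 1] +
    0.5 * (mig_prev[A] + mig_prev[A + 1] + mig_curr[A + 1])
  pop[A + 1] <- ent_term * s_mean[A]
  deaths[A + 1] <- ent_term * (1 - s_mean[A])

  list(pop = pop, deaths = deaths)
}

#' Survive the interval's birth cohort into age 0
#'
#' The mid-year age-0 population is the interval's births of each sex
#' multiplied by the sex-specific birth-to-mid-year survival factor taken
#' from the life table's first person-years entry (`L0 / l0`).
#'
#' @param births_by_sex Named vector `c(male =, female =)` of interval
#'   births.
#' @param infant_survival Named vector of per-sex factors in (0, 1] (the
#'   `infant` element of [survival_ratios()]).
#' @return Named vector of age-0 counts by sex, plus attribute `deaths`
#'   (infant deaths by sex).
#' @export
infant_population <- function(births_by_sex, infant_survival) {
  assert_that(all(infant_survival > 0 & infant_survival <= 1),
              "infant survival factors must lie in (0, 1]")
  assert_that(all(births_by_sex >= 0), "births must be non-negative")
  s <- infant_survival[names(births_by_sex)]
  out <- births_by_sex * s
  attr(out, "deaths") <- births_by_sex - out
  out
}

# fit life tables for one year of a scenario, cached by (sex, e0) so that
# scenarios with constant mortality fit each table once
.year_tables <- function(scenario, year, cache) {
  lapply(stats::setNames(SEXES, SEXES), function(sx) {
    e0 <- scenario$series[[paste0("e0_", substr(sx, 1, 1))]][
      as.character(year)]
    key <- sprintf("%s|%.9f", sx, e0)
    if (is.null(cache[[key]])) {
      cache[[key]] <- survival_ratios(fit_life_table(e0, sx))
    }
    cache[[key]]
  })
}

#' Run the full cohort-component projection
#'
#' Iterates the annual step over the scenario horizon: per-sex life tables
#' are fitted to each year's life-expectancy input, cohorts advanced,
#' interval births generated from the fertility inputs, split by the sex
#' ratio at birth, and survived into age 0. Mid-year populations, annual
#' step, horizon inclusive of both endpoints. Deterministic: identical
#' inputs give identical results.
#'
#' @param scenario A `scenario_spec` (see [build_emphasis()]).
#' @param base An `age_sex_table` for the scenario's start year.
#' @param horizon Number of years to project beyond the base year; defaults
#'   to the scenario's full horizon.
#' @param migration A `migration_schedule` or `NULL` for zero net migration.
#' @return A `projection_result`: list with `scenario_id`, `years`, `pop`
#'   (array ages x sexes x years) and `vital` (data frame of interval
#'   births by sex, deaths, and net migration, labelled by ending year).
#' @export
project <- function(scenario, base, horizon = NULL, migration = NULL) {
  assert_that(inherits(scenario, "scenario_spec"),
              "`scenario` must be a scenario_spec")
  assert_that(inherits(base, "age_sex_table"),
              "`base` must be an age_sex_table")
  years_all <- scenario$years
  assert_that(base$year[1] == years_all[1],
              "base table year (%d) must equal scenario start (%d)",
              base$year[1], years_all[1])
  horizon <- horizon %||% (length(years_all) - 1L)
  assert_that(horizon >= 0 && horizon <= length(years_all) - 1L,
              "horizon must lie within the scenario's %d-year span",
              length(years_all) - 1L)
  years <- years_all[1:(horizon + 1L)]
  if (is.null(migration)) migration <- zero_migration(years)

  nA <- length(AGES)
  pop <- array(NA_real_, dim = c(nA, 2L, length(years)),
               dimnames = list(age = AGES, sex = SEXES, year = years))
  pop[, "female", 1] <- sex_counts(base, "female")
  pop[, "male", 1] <- sex_counts(base, "male")

  vital <- data.frame(year = integer(0), births_f = numeric(0),
                      births_m = numeric(0), deaths_total = numeric(0),
                      net_migration = numeric(0))
  cache <- new.env(parent = emptyenv())
  sr_prev <- .year_tables(scenario, years[1], cache)

  for (i in seq_along(years)[-1]) {
    yr_prev <- years[i - 1]; yr <- years[i]
    sr_curr <- tryCatch(
      .year_tables(scenario, yr, cache),
      error = function(e) stop_dividendsim(
        "year %d: %s", yr, conditionMessage(e)))

    deaths_total <- 0
    for (sx in SEXES) {
      adv <- advance_cohorts(
        pop[, sx, i - 1],
        sr_prev[[sx]]$advance, sr_curr[[sx]]$advance,
        .mig_slice(migration, yr_prev, sx), .mig_slice(migration, yr, sx))
      pop[, sx, i] <- adv$pop
      deaths_total <- deaths_total + sum(adv$deaths)
    }

    key_prev <- as.character(yr_prev); key <- as.character(yr)
    births_total <- compute_births(
      pop[, "female", i - 1], pop[, "female", i],
      scenario$series$tfr[key_prev], scenario$series$tfr[key],
      scenario$fert_dist[, key_prev], scenario$fert_dist[, key])
    bsx <- split_births_by_sex(births_total,
                               scenario$series$srb[key])
    infant_factor <- c(
      female = 0.5 * (sr_prev$female$infant + sr_curr$female$infant),
      male = 0.5 * (sr_prev$male$infant + sr_curr$male$infant))
    age0 <- infant_population(bsx[c("female", "male")], infant_factor)
    pop["0", "female", i] <- age0[["female"]]
    pop["0", "male", i] <- age0[["male"]]
    deaths_total <- deaths_total + sum(attr(age0, "deaths"))

    vital <- rbind(vital, data.frame(
      year = yr, births_f = bsx[["female"]], births_m = bsx[["male"]],
      deaths_total = deaths_total,
      net_migration = sum(vapply(SEXES, function(sx) {
        mp <- .mig_slice(migration, yr_prev, sx)
        mc <- .mig_slice(migration, yr, sx)
        0.5 * (sum(mp) + sum(mc[-1]))   # age-0 migrants enter with births
      }, numeric(1)))))
    sr_prev <- sr_curr
  }
  rownames(vital) <- NULL
  structure(list(scenario_id = scenario$id, years = years,
                 pop = pop, vital = vital),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf(
    "<projection_result> scenario '%s', %d years (%d-%d), final total %.0f\n",
    x$scenario_id, length(x$years), x$years[1],
    x$years[length(x$years)], sum(x$pop[, , length(x$years)])))
  invisible(x)
}

#' Per-year total population of a projection
#' @param result A `projection_result`.
#' @return Named numeric vector over years.
#' @export
projected_totals <- function(result) {
  apply(result$pop, 3, sum)
}

#' Extract one projected year as an `age_sex_table`
#' @param result A `projection_result`.
#' @param year Calendar year present in the result.
#' @return An `age_sex_table`.
#' @export
projection_year_table <- function(result, year) {
  i <- match(year, result$years)
  assert_that(!is.na(i), "year %d not in projection", year)
  age_sex_table(year, female = result$pop[, "female", i],
                male = result$pop[, "male", i])
}

#' Write projection outputs to CSV
#'
#' Long population CSV (`scenario, year, age, sex, population`) and a
#' vital-events CSV (`scenario, year, births_f, births_m, deaths_total`).
#'
#' @param result A `projection_result`.
#' @param pop_path,vital_path Output file paths.
#' @export
write_projection_csv <- function(result, pop_path, vital_path) {
  grid <- expand.grid(age = AGES, sex = SEXES, year = result$years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$population <- as.vector(result$pop)
  grid <- cbind(scenario = result$scenario_id,
                grid[, c("year", "age", "sex", "population")])
  utils::write.csv(grid, pop_path, row.names = FALSE)
  vt <- cbind(scenario = result$scenario_id, result$vital)
  utils::write.csv(vt, vital_path, row.names = FALSE)
  invisible(c(pop_path, vital_path))
}
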
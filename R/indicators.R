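# Demographic and economic indicators computed from a projection:
# dependency ratios, the demographic window of opportunity, labour force,
# service requirements, GDP, GDP per capita and the dividend between two
# scenarios.

.band_matrix <- function(result) {
  # persons by dependency band and year
  pop_by_age <- apply(result$pop, c(1, 3), sum)
  ages <- as.integer(rownames(pop_by_age))
  rbind(child = colSums(pop_by_age[ages <= 14, , drop = FALSE]),
        working = colSums(pop_by_age[ages >= 15 & ages <= 64, , drop = FALSE]),
        old = colSums(pop_by_age[ages >= 65, , drop = FALSE]))
}

#' Dependency ratios per projected year
#'
#' Child (0-14), old-age (65+) and total dependants per 100 persons of
#' working age (15-64); the total is the sum of the two components.
#'
#' @param result A `projection_result`.
#' @return Data frame with `year`, `dep_child`, `dep_old`, `dep_total`.
#' @export
dependency_ratios <- function(result) {
  b <- .band_matrix(result)
  if (any(b["working", ] <= 0)) {
    stop_dividendsim("zero working-age population in year %d",
                     result$years[which(b["working", ] <= 0)[1]])
  }
  data.frame(year = result$years,
             dep_child = 100 * b["child", ] / b["working", ],
             dep_old = 100 * b["old", ] / b["working", ],
             dep_total = 100 * (b["child", ] + b["old", ]) / b["working", ],
             row.names = NULL)
}

#' Population shares by dependency band
#'
#' @param result A `projection_result`.
#' @return Data frame with `year`, `share_0_14`, `share_15_64`,
#'   `share_65p` (fractions of total population).
#' @export
population_shares <- function(result) {
  b <- .band_matrix(result)
  tot <- colSums(b)
  data.frame(year = result$years,
             share_0_14 = b["child", ] / tot,
             share_15_64 = b["working", ] / tot,
             share_65p = b["old", ] / tot,
             row.names = NULL)
}

#' Detect the demographic window of opportunity
#'
#' The UN window opens in the first year in which the under-15 share of
#' the population falls below 30 percent while the 65-plus share is below
#' 15 percent, and closes with the last consecutive year thereafter
#' satisfying both conditions. The effective window keeps the same opening
#' year but closes at the year of minimum total dependency ratio (the point
#' after which ageing drives the overall dependency burden back up); ties
#' break toward the earliest year.
#'
#' @param result A `projection_result` spanning at least 3 years, or a data
#'   frame carrying `year`, `share_0_14`, `share_65p`, `dep_total` (so
#'   constructed share trajectories can be screened directly).
#' @return A `window_report`: list with `un_open_year`, `un_close_year`,
#'   `effective_open_year`, `effective_close_year`, and `attained`
#'   (`FALSE` with `NA` years when the conditions are never met).
#' @export
window_of_opportunity <- function(result) {
  if (inherits(result, "projection_result")) {
    assert_that(length(result$years) >= 3,
                "window detection needs at least 3 projected years")
    df <- cbind(population_shares(result),
                dep_total = dependency_ratios(result)$dep_total)
  } else {
    df <- result
    need <- c("year", "share_0_14", "share_65p", "dep_total")
    assert_that(all(need %in% names(df)),
                "data frame input must carry %s", paste(need, collapse = ", "))
    assert_that(nrow(df) >= 3, "window detection needs at least 3 years")
  }
  ok <- df$share_0_14 < 0.30 & df$share_65p < 0.15
  if (!any(ok)) {
    return(structure(list(un_open_year = NA_integer_,
                          un_close_year = NA_integer_,
                          effective_open_year = NA_integer_,
                          effective_close_year = NA_integer_,
                          attained = FALSE),
                     class = "window_report"))
  }
  open_i <- which(ok)[1]
  run_end <- open_i
  while (run_end < nrow(df) && ok[run_end + 1]) run_end <- run_end + 1
  eff_close_i <- which.min(df$dep_total)  # earliest index on ties
  structure(list(un_open_year = df$year[open_i],
                 un_close_year = df$year[run_end],
                 effective_open_year = df$year[open_i],
                 effective_close_year = df$year[eff_close_i],
                 attained = TRUE),
            class = "window_report")
}

#' @export
print.window_report <- function(x, ...) {
  if (!x$attained) {
    cat("<window_report> demographic window of opportunity not attained\n")
  } else {
    cat(sprintf(
      "<window_report> UN window %d-%d; effective window %d-%d\n",
      x$un_open_year, x$un_close_year,
      x$effective_open_year, x$effective_close_year))
  }
  invisible(x)
}

#' Project GDP at exogenous growth rates
#'
#' Compounds the base-year GDP forward: `GDP(t) = GDP(t-1) * (1 + g(t))`.
#' Population growth does not feed back into GDP.
#'
#' @param base_gdp GDP in the base year (constant-price currency units).
#' @param growth_series Named annual growth fractions; the base year's own
#'   entry is ignored (its GDP is `base_gdp`).
#' @return Named GDP series over the years of `growth_series`.
#' @export
#' @examples
#' project_gdp(100, setNames(rep(0.02, 11), 2000:2010))[["2010"]]  # 121.899
project_gdp <- function(base_gdp, growth_series) {
  assert_that(base_gdp > 0, "`base_gdp` must be positive")
  assert_that(all(growth_series > -1), "growth rates must exceed -1")
  n <- length(growth_series)
  gdp <- base_gdp * cumprod(c(1, 1 + growth_series[-1]))
  stats::setNames(gdp, names(growth_series))
}

#' GDP per capita from a GDP series and a projection
#'
#' @param gdp Named GDP series.
#' @param result A `projection_result` over the same years, or a named
#'   total-population vector.
#' @return Named per-capita series (currency per person).
#' @export
gdp_per_capita <- function(gdp, result) {
  pop <- if (inherits(result, "projection_result")) {
    projected_totals(result)
  } else result
  assert_that(identical(names(gdp), names(pop)),
              "GDP and population series must cover identical years")
  assert_that(all(pop > 0), "population must be positive in every year")
  gdp / pop
}

#' Demographic dividend between two scenarios
#'
#' The year-wise difference in GDP per capita, emphasis minus as-usual.
#'
#' @param emphasis,as_usual Named per-capita series over identical years.
#' @return Data frame with `year` and `dividend` (same currency units as
#'   the inputs).
#' @export
#' @examples
#' dividend(setNames(548.60, 2061), setNames(382.75, 2061))  # 165.85
dividend <- function(emphasis, as_usual) {
  assert_that(identical(names(emphasis), names(as_usual)),
              "per-capita series must cover identical years")
  data.frame(year = as.integer(names(emphasis)),
             dividend = unname(emphasis - as_usual),
             row.names = NULL)
}

#' Labour force by sex and year
#'
#' Workers are participation rates applied to the 10-14 and 15-64 age
#' bands: `workers = pop(10-14) * LFPR_10_14 + pop(15-64) * LFPR_15_64`
#' per sex.
#'
#' @param result A `projection_result`.
#' @param scenario The `scenario_spec` carrying the LFPR series.
#' @return Data frame with `year`, `workers_f`, `workers_m`,
#'   `workers_total`.
#' @export
labour_force <- function(result, scenario) {
  yrs <- as.character(result$years)
  ages <- as.integer(dimnames(result$pop)$age)
  band <- function(sx, lo, hi) {
    colSums(result$pop[ages >= lo & ages <= hi, sx, , drop = FALSE])
  }
  for (f in .FRACTION_FIELDS[1:4]) {
    assert_that(all(scenario$series[[f]][yrs] >= 0 &
                    scenario$series[[f]][yrs] <= 1),
                "LFPR series `%s` must lie in [0, 1]", f)
  }
  wf <- band("female", 10, 14) * scenario$series$lfpr_f_10_14[yrs] +
        band("female", 15, 64) * scenario$series$lfpr_f_15_64[yrs]
  wm <- band("male", 10, 14) * scenario$series$lfpr_m_10_14[yrs] +
        band("male", 15, 64) * scenario$series$lfpr_m_15_64[yrs]
  data.frame(year = result$years, workers_f = as.numeric(wf),
             workers_m = as.numeric(wm),
             workers_total = as.numeric(wf + wm), row.names = NULL)
}

#' Service requirements implied by the goalpost ratios
#'
#' Teachers required to serve the enrolled school-age population at the
#' student-teacher goalpost, doctors required at the population-per-doctor
#' goalpost, and urban dwellings required at the urban-share and
#' persons-per-household goalposts.
#'
#' @param result A `projection_result`.
#' @param scenario The `scenario_spec` carrying `ger`,
#'   `students_per_teacher`, `pop_per_doctor`, `urban_share`,
#'   `persons_per_household`.
#' @param school_ages Integer ages counted as school-age (default 6-15,
#'   entry at 6 with five years each of primary and secondary schooling).
#' @return Data frame with `year`, `teachers`, `doctors`,
#'   `urban_dwellings`.
#' @export
service_requirements <- function(result, scenario, school_ages = 6:15) {
  yrs <- as.character(result$years)
  spt <- scenario$series$students_per_teacher[yrs]
  ppd <- scenario$series$pop_per_doctor[yrs]
  pph <- scenario$series$persons_per_household[yrs]
  assert_that(all(spt > 0) && all(ppd > 0) && all(pph > 0),
              "service ratio goalposts must be positive")
  ages <- as.integer(dimnames(result$pop)$age)
  school_pop <- colSums(apply(
    result$pop[ages %in% school_ages, , , drop = FALSE], c(1, 3), sum))
  tot <- projected_totals(result)
  enrolled <- school_pop * scenario$series$ger[yrs]
  data.frame(year = result$years,
             teachers = as.numeric(enrolled / spt),
             doctors = as.numeric(tot / ppd),
             urban_dwellings = as.numeric(
               tot * scenario$series$urban_share[yrs] / pph),
             row.names = NULL)
}

#' Assemble the per-scenario indicators table
#'
#' One row per year: population shares, dependency ratios, GDP and GDP per
#' capita.
#'
#' @param result A `projection_result`.
#' @param scenario Its `scenario_spec`.
#' @param base_gdp Base-year GDP (constant-price currency units; thousand
#'   rupees if per-capita outputs are to be read in thousand rupees per
#'   person).
#' @return Data frame with columns `scenario, year, share_0_14,
#'   share_15_64, share_65p, dep_child, dep_old, dep_total, gdp, gdp_pc`.
#' @export
scenario_indicators <- function(result, scenario, base_gdp) {
  shares <- population_shares(result)
  deps <- dependency_ratios(result)
  yrs <- as.character(result$years)
  gdp <- project_gdp(base_gdp, scenario$series$gdp_growth[yrs])
  pc <- gdp_per_capita(gdp, result)
  cbind(scenario = result$scenario_id,
        shares,
        deps[, c("dep_child", "dep_old", "dep_total")],
        gdp = unname(gdp), gdp_pc = unname(pc))
}
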
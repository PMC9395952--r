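# Scenario layer: bundles of annual input trajectories built from sparse
# (year, value) goalpost anchors. Two ready-made builders mirror the study
# design: "as-usual" freezes every demographic input at its base-year value
# while socio-economic goalposts still progress, and "emphasis" moves the
# demographic inputs along their stated goalpost paths as well.

#' Interpolate a goalpost trajectory to annual values
#'
#' Linear interpolation between consecutive anchors, constant extension
#' before the first and after the last anchor; anchor years are reproduced
#' exactly.
#'
#' @param anchors A list of `c(year, value)` pairs (or a 2-column matrix),
#'   years sorted and unique; at least one anchor.
#' @param years Integer vector of calendar years to evaluate.
#' @return Named numeric vector over `years`.
#' @export
#' @examples
#' interpolate_trajectory(list(c(2000, 0), c(2010, 10)), 2000:2010)
interpolate_trajectory <- function(anchors, years) {
  if (is.list(anchors)) anchors <- do.call(rbind, anchors)
  assert_that(is.matrix(anchors) && nrow(anchors) >= 1 && ncol(anchors) == 2,
              "`anchors` must be a non-empty list of c(year, value) pairs")
  ax <- anchors[, 1]; ay <- anchors[, 2]
  assert_that(!is.unsorted(ax, strictly = TRUE),
              "anchor years must be sorted and unique")
  out <- if (nrow(anchors) == 1L) rep(ay, length(years)) else {
    stats::approx(ax, ay, xout = years, rule = 2)$y
  }
  stats::setNames(out, years)
}

# discretized unimodal fertility distribution over ages 15..49
.fert_dist_vector <- function(mode, spread) {
  assert_that(mode >= 15 && mode <= 49,
              "fertility mode age must lie in [15, 49]")
  assert_that(spread > 0, "fertility spread must be positive")
  w <- stats::dnorm(15:49, mean = mode, sd = spread)
  stats::setNames(w / sum(w), 15:49)
}

# fields whose annual series are fractions constrained to [0, 1]
.FRACTION_FIELDS <- c("lfpr_m_15_64", "lfpr_f_15_64",
                      "lfpr_m_10_14", "lfpr_f_10_14",
                      "urban_share", "ger")
.SERIES_FIELDS <- c("tfr", "srb", "e0_f", "e0_m", "gdp_growth",
                    .FRACTION_FIELDS,
                    "students_per_teacher", "pop_per_doctor",
                    "persons_per_household")

#' Build a scenario from goalpost anchors
#'
#' The generic constructor behind [build_as_usual()] and
#' [build_emphasis()]: every input field is given as a sparse anchor list
#' and expanded to an annual series with [interpolate_trajectory()]. The
#' age distribution of fertility is parameterized by `dist_mode` and
#' `dist_spread` anchors (a discretized normal on ages 15-49, renormalized
#' to sum to 1 each year).
#'
#' @param id Scenario identifier string.
#' @param horizon `c(start, end)` calendar years, end >= start.
#' @param anchors Named list of anchor lists, one per field:
#'   `tfr`, `srb`, `e0_f`, `e0_m`, `gdp_growth`, `lfpr_m_15_64`,
#'   `lfpr_f_15_64`, `lfpr_m_10_14`, `lfpr_f_10_14`, `students_per_teacher`,
#'   `pop_per_doctor`, `urban_share`, `persons_per_household`, `ger`,
#'   `dist_mode`, `dist_spread`. Each is a list of `c(year, value)` pairs.
#' @param migration_mode `"zero"` (default) or `"file"`.
#' @param interpolation Interpolation rule id; only `"linear"` is built in.
#' @return A `scenario_spec`: list with `id`, `years`, `series` (named
#'   annual vectors), `fert_dist` (35 x years matrix, columns summing to 1),
#'   `anchors` (as supplied, for lossless serialization), `migration_mode`,
#'   `interpolation`.
#' @export
scenario_from_anchors <- function(id, horizon, anchors,
                                  migration_mode = "zero",
                                  interpolation = "linear") {
  assert_that(interpolation == "linear",
              "unknown interpolation rule '%s'", interpolation)
  assert_that(length(horizon) == 2 && horizon[2] >= horizon[1],
              "`horizon` must be c(start, end) with end >= start")
  years <- as.integer(horizon[1]):as.integer(horizon[2])
  missing_fields <- setdiff(c(.SERIES_FIELDS, "dist_mode", "dist_spread"),
                            names(anchors))
  assert_that(length(missing_fields) == 0,
              "missing anchor field(s): %s",
              paste(missing_fields, collapse = ", "))

  series <- lapply(stats::setNames(.SERIES_FIELDS, .SERIES_FIELDS),
                   function(f) interpolate_trajectory(anchors[[f]], years))
  assert_that(all(series$srb > 0), "SRB must be positive")
  assert_that(all(series$tfr >= 0), "TFR must be non-negative")
  for (f in .FRACTION_FIELDS) {
    assert_that(all(series[[f]] >= 0 & series[[f]] <= 1),
                "series `%s` must lie in [0, 1]", f)
  }

  mode_s <- interpolate_trajectory(anchors$dist_mode, years)
  spread_s <- interpolate_trajectory(anchors$dist_spread, years)
  fert_dist <- vapply(seq_along(years),
                      function(i) .fert_dist_vector(mode_s[i], spread_s[i]),
                      numeric(35))
  dimnames(fert_dist) <- list(age = 15:49, year = years)

  structure(list(id = id, years = years, series = series,
                 fert_dist = fert_dist, anchors = anchors,
                 migration_mode = migration_mode,
                 interpolation = interpolation),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "<scenario_spec> '%s', %d-%d; TFR %.2f -> %.2f, SRB %.0f -> %.0f, e0(f) %.1f -> %.1f\n",
    x$id, x$years[1], x$years[length(x$years)],
    x$series$tfr[1], x$series$tfr[length(x$years)],
    x$series$srb[1], x$series$srb[length(x$years)],
    x$series$e0_f[1], x$series$e0_f[length(x$years)]))
  invisible(x)
}

#' Default base-year inputs and goalpost anchors
#'
#' The bundled India-like configuration: base year 2001 with TFR 3.14, sex
#' ratio at birth 111, life expectancy 63.9 (f) / 62.3 (m), and goalposts
#' for 2061 taken from the study design (TFR via replacement level 2.1 at
#' 2020 down to 1.74 at 2060; SRB stabilizing at 108; e0 reaching 78 (f) /
#' 75 (m); labour-force participation at 15-64 reaching 0.86 (m) / 0.65
#' (f) and at 10-14 falling to 0.001; annual GDP growth declining to 0.02;
#' student-teacher ratio 13, population per doctor 300, urban share 0.70,
#' 2 persons per urban household, gross enrolment ratio 1).
#'
#' @param start,end Horizon years.
#' @return A list with `horizon` and the anchor lists used by
#'   [build_as_usual()] and [build_emphasis()].
#' @export
default_inputs <- function(start = 2001, end = 2061) {
  list(
    horizon = c(start, end),
    base = list(tfr = 3.14, srb = 111, e0_f = 63.9, e0_m = 62.3,
                dist_mode = 25, dist_spread = 5.5),
    demographic_goalposts = list(
      tfr = list(c(2001, 3.14), c(2020, 2.1), c(2060, 1.74)),
      srb = list(c(2001, 111), c(2061, 108)),
      e0_f = list(c(2001, 63.9), c(2061, 78)),
      e0_m = list(c(2001, 62.3), c(2061, 75)),
      dist_mode = list(c(2001, 25), c(2061, 29)),
      dist_spread = list(c(2001, 5.5), c(2061, 5.0))),
    socio_economic = list(
      gdp_growth = list(c(2001, 0.07), c(2061, 0.02)),
      lfpr_m_15_64 = list(c(2001, 0.80), c(2061, 0.86)),
      lfpr_f_15_64 = list(c(2001, 0.30), c(2061, 0.65)),
      lfpr_m_10_14 = list(c(2001, 0.05), c(2061, 0.001)),
      lfpr_f_10_14 = list(c(2001, 0.05), c(2061, 0.001)),
      students_per_teacher = list(c(2001, 40), c(2061, 13)),
      pop_per_doctor = list(c(2001, 1700), c(2061, 300)),
      urban_share = list(c(2001, 0.28), c(2061, 0.70)),
      persons_per_household = list(c(2001, 5), c(2061, 2)),
      ger = list(c(2001, 0.8), c(2061, 1.0)))
  )
}

#' Build the demographic-as-usual scenario
#'
#' Freezes every demographic input (TFR, fertility distribution, SRB, life
#' expectancy) at its base-year value for the whole horizon, while the
#' socio-economic goalpost series (GDP growth, labour-force participation,
#' education/health/urbanization ratios) still follow their anchors.
#'
#' @param inputs A configuration list as returned by [default_inputs()];
#'   must carry `horizon`, `base` (base-year demographic values) and
#'   `socio_economic` anchor lists.
#' @return A `scenario_spec` with id `"as_usual"`.
#' @export
#' @examples
#' s <- build_as_usual(default_inputs())
#' range(s$series$tfr)  # constant 3.14
build_as_usual <- function(inputs = default_inputs()) {
  base <- inputs$base
  for (f in c("tfr", "srb", "e0_f", "e0_m", "dist_mode", "dist_spread")) {
    assert_that(!is.null(base[[f]]),
                "missing base-year value for field `%s`", f)
  }
  start <- inputs$horizon[1]
  demog <- lapply(base, function(v) list(c(start, v)))
  scenario_from_anchors("as_usual", inputs$horizon,
                        c(demog, inputs$socio_economic))
}

#' Build the demographic-emphasis scenario
#'
#' Moves every demographic input along its goalpost path (fertility
#' declining through replacement level to below-replacement, SRB
#' normalizing, life expectancy rising) together with the same
#' socio-economic goalpost series as the as-usual scenario.
#'
#' @param inputs A configuration list as returned by [default_inputs()];
#'   must carry `horizon`, `demographic_goalposts` and `socio_economic`.
#' @return A `scenario_spec` with id `"emphasis"`.
#' @export
#' @examples
#' s <- build_emphasis(default_inputs())
#' s$series$tfr["2020"]  # 2.1, replacement level
build_emphasis <- function(inputs = default_inputs()) {
  assert_that(!is.null(inputs$demographic_goalposts),
              "missing `demographic_goalposts` anchors")
  scenario_from_anchors("emphasis", inputs$horizon,
                        c(inputs$demographic_goalposts,
                          inputs$socio_economic))
}

# ---------------------------------------------------------------------------
# YAML serialization (anchors round-trip losslessly; derived series are
# rebuilt deterministically on read)
# ---------------------------------------------------------------------------

#' Write a scenario to YAML
#'
#' Serializes the scenario's anchors, horizon, migration mode and
#' interpolation rule; reading the file back with [scenario_from_yaml()]
#' rebuilds an identical spec.
#'
#' @param scenario A `scenario_spec`.
#' @param path Output path.
#' @export
scenario_to_yaml <- function(scenario, path) {
  obj <- list(
    scenario_id = scenario$id,
    horizon = list(start = scenario$years[1],
                   end = scenario$years[length(scenario$years)]),
    interpolation = scenario$interpolation,
    migration = list(mode = scenario$migration_mode),
    anchors = lapply(scenario$anchors,
                     function(a) lapply(a, as.numeric))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a scenario from YAML
#'
#' @param path A YAML file written by [scenario_to_yaml()] (or hand-written
#'   with the same layout: `scenario_id`, `horizon: {start, end}`,
#'   `anchors:` with `[[year, value], ...]` per field).
#' @return A `scenario_spec`.
#' @export
scenario_from_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  assert_that(!is.null(obj$scenario_id) && !is.null(obj$horizon),
              "scenario YAML must carry scenario_id and horizon")
  anchors <- lapply(obj$anchors, function(a) lapply(a, as.numeric))
  scenario_from_anchors(
    obj$scenario_id,
    c(obj$horizon$start, obj$horizon$end),
    anchors,
    migration_mode = obj$migration$mode %||% "zero",
    interpolation = obj$interpolation %||% "linear")
}
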
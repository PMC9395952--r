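# Synthetic inputs: India-like base pyramids, fertility schedules and
# scenario bundles so the full pipeline runs without any external data.
# The base pyramid is a stable population: age shape c(a) proportional to
# exp(-r a) * L(a), with r either supplied or solved from the discrete
# Euler-Lotka equation for the configured fertility and mortality.

#' Synthetic input configuration
#'
#' @param seed Integer seed; all randomness in the generators flows from
#'   it (noise draws only - rate schedules are never perturbed).
#' @param base_total Total persons in the base-year pyramid.
#' @param growth_rate Intrinsic growth rate r per year for the stable age
#'   shape; `NULL` (default) solves r from the Euler-Lotka equation for the
#'   base-year fertility and mortality, so the pyramid is self-consistent.
#' @param e0_f,e0_m Target life expectancy by sex, years.
#' @param tfr_anchors TFR goalpost anchors, list of `c(year, value)`.
#' @param fert_mode,fert_spread Mode age and spread (years) of the
#'   unimodal age distribution of fertility on 15-49.
#' @param srb Sex ratio at birth, male per 100 female.
#' @param noise Relative s.d. of multiplicative lognormal noise applied to
#'   base-population counts (0 = noiseless).
#' @param base_year First calendar year.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, base_total = 1e6,
                             growth_rate = NULL,
                             e0_f = 63.9, e0_m = 62.3,
                             tfr_anchors = list(c(2001, 3.14)),
                             fert_mode = 25, fert_spread = 5.5,
                             srb = 111, noise = 0,
                             base_year = 2001) {
  assert_that(base_total > 0, "`base_total` must be positive")
  assert_that(fert_spread > 0, "`fert_spread` must be positive")
  assert_that(noise >= 0, "`noise` must be non-negative")
  assert_that(srb > 0, "`srb` must be positive")
  structure(list(seed = as.integer(seed), base_total = base_total,
                 growth_rate = growth_rate, e0_f = e0_f, e0_m = e0_m,
                 tfr_anchors = tfr_anchors, fert_mode = fert_mode,
                 fert_spread = fert_spread, srb = srb, noise = noise,
                 base_year = as.integer(base_year)),
            class = "synthetic_config")
}

#' Intrinsic growth rate from the discrete Euler-Lotka equation
#'
#' Solves for the growth rate r satisfying
#' `sum_a exp(-r (a + 0.5)) * ffab * TFR * dist(a) * L(a) / l0 = 1`,
#' where `ffab` is the female fraction at birth implied by the sex ratio at
#' birth and the sum runs over reproductive ages; the female life table
#' supplies the survivorship person-years.
#'
#' @param tfr Total fertility rate, children per woman.
#' @param fert_dist Normalized fertility distribution named by age 15..49.
#' @param srb Sex ratio at birth (male per 100 female).
#' @param lt_female Female `life_table`.
#' @return Intrinsic growth rate r (per year).
#' @export
intrinsic_growth_rate <- function(tfr, fert_dist, srb, lt_female) {
  ffab <- 100 / (100 + srb)
  ages <- as.integer(names(fert_dist))
  Lx <- lt_female$Lx[match(ages, lt_female$age)] / lt_female$lx[1]
  net_mat <- ffab * tfr * fert_dist * Lx      # net maternity by age
  f <- function(r) sum(exp(-r * (ages + 0.5)) * net_mat) - 1
  stats::uniroot(f, interval = c(-0.2, 0.2), tol = 1e-12)$root
}

#' Generate a stable base-year population pyramid
#'
#' The age shape is the stable population `c(a) = exp(-r a) * L(a)` per
#' sex, with sexes weighted so that the sex ratio of the birth cohort
#' matches the configured SRB; the shape is scaled to `base_total` and,
#' optionally, perturbed by multiplicative lognormal noise (counts only).
#' Reproducible: a fixed seed gives a bit-identical table.
#'
#' @param config A [synthetic_config()].
#' @return An `age_sex_table` for the base year. The realized intrinsic
#'   rate is attached as attribute `growth_rate`.
#' @export
make_base_population <- function(config) {
  assert_that(inherits(config, "synthetic_config"),
              "`config` must be a synthetic_config")
  lt <- list(female = fit_life_table(config$e0_f, "female"),
             male = fit_life_table(config$e0_m, "male"))
  fert <- make_fertility_schedule(config)
  tfr0 <- fert$tfr[as.character(config$base_year)]
  r <- config$growth_rate %||%
    intrinsic_growth_rate(tfr0, fert$dist[, as.character(config$base_year)],
                          config$srb, lt$female)
  ffab <- 100 / (100 + config$srb)
  shape <- lapply(lt, function(l) {
    stats::setNames(exp(-r * (l$age + 0.5)) * l$Lx / l$lx[1], l$age)
  })
  # births of each sex scale its stable stream
  shape$female <- ffab * shape$female
  shape$male <- (1 - ffab) * shape$male
  scale <- config$base_total / (sum(shape$female) + sum(shape$male))
  f <- shape$female * scale
  m <- shape$male * scale
  if (config$noise > 0) {
    sdlog <- sqrt(log(1 + config$noise^2))
    noise_draw <- withr::with_seed(config$seed, {
      stats::rlnorm(2 * length(AGES), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    })
    f <- f * noise_draw[seq_along(AGES)]
    m <- m * noise_draw[length(AGES) + seq_along(AGES)]
  }
  out <- age_sex_table(config$base_year, female = f, male = m)
  attr(out, "growth_rate") <- r
  out
}

#' Generate a fertility schedule from a configuration
#'
#' The age distribution of fertility is a discretized unimodal (normal)
#' density on ages 15-49, renormalized to sum to 1; the TFR series comes
#' from the configured anchors via [interpolate_trajectory()].
#'
#' @param config A [synthetic_config()].
#' @param years Years to cover (default: 61 years from the base year).
#' @return A list with `tfr` (named annual series) and `dist`
#'   (35 x years matrix, columns summing to 1).
#' @export
make_fertility_schedule <- function(config,
                                    years = config$base_year + 0:60) {
  assert_that(config$fert_mode >= 15 && config$fert_mode <= 49,
              "fertility mode age must lie in [15, 49]")
  tfr <- interpolate_trajectory(config$tfr_anchors, years)
  d <- .fert_dist_vector(config$fert_mode, config$fert_spread)
  dist <- matrix(d, nrow = 35, ncol = length(years),
                 dimnames = list(age = 15:49, year = years))
  list(tfr = tfr, dist = dist)
}

#' Bundle a study-like base population and scenario pair
#'
#' Produces a young, high-fertility (TFR 3.14-consistent) stable base
#' pyramid together with the as-usual and emphasis scenario specs carrying
#' the bundled goalpost anchors. Running the projection and economy stages
#' on this bundle yields a positive demographic dividend after the base
#' year: both scenarios share one exogenous GDP path while the emphasis
#' population grows more slowly.
#'
#' @param config A [synthetic_config()]; its base-year demographic fields
#'   feed both the pyramid and the scenarios' base anchors.
#' @param base_gdp_per_capita Base-year GDP per capita in thousand
#'   constant-price rupees (default 42.55); the base GDP is this value
#'   times the generated base population.
#' @return A list with `base` (an `age_sex_table`), `as_usual` and
#'   `emphasis` (`scenario_spec`s), and `base_gdp`.
#' @export
make_paper_like_inputs <- function(config = synthetic_config(),
                                   base_gdp_per_capita = 42.55) {
  base <- make_base_population(config)
  inputs <- default_inputs(config$base_year, config$base_year + 60)
  inputs$base$tfr <- interpolate_trajectory(
    config$tfr_anchors, config$base_year)[[1]]
  inputs$base$srb <- config$srb
  inputs$base$e0_f <- config$e0_f
  inputs$base$e0_m <- config$e0_m
  inputs$base$dist_mode <- config$fert_mode
  inputs$base$dist_spread <- config$fert_spread
  # emphasis demographic paths start from the same base values
  inputs$demographic_goalposts$tfr[[1]] <-
    c(config$base_year, inputs$base$tfr)
  inputs$demographic_goalposts$srb[[1]] <- c(config$base_year, config$srb)
  inputs$demographic_goalposts$e0_f[[1]] <- c(config$base_year, config$e0_f)
  inputs$demographic_goalposts$e0_m[[1]] <- c(config$base_year, config$e0_m)
  inputs$demographic_goalposts$dist_mode[[1]] <-
    c(config$base_year, config$fert_mode)
  inputs$demographic_goalposts$dist_spread[[1]] <-
    c(config$base_year, config$fert_spread)
  list(base = base,
       as_usual = build_as_usual(inputs),
       emphasis = build_emphasis(inputs),
       base_gdp = base_gdp_per_capita * total_population(base))
}
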
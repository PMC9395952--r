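# Life tables: a bundled synthetic standard schedule and a Brass logit
# relational model that warps it to any target life expectancy at birth.
#
# The relational mechanism mirrors how goalpost-driven projection packages
# turn a single e0 input into a full survival schedule: pick a standard
# survivorship column l^s(x), transform Y(x) = logit(1 - l(x)/l(0)), and fit
# Y(x) = alpha + beta * Y^s(x). Here beta is fixed at 1 and alpha is found by
# a one-dimensional root search so the fitted table reproduces the target e0.

# Siler hazard: infant decline + background + Gompertz senescence.
# Parameters chosen once to give an early-2000s South-Asia-like schedule
# (e0 in the low 60s, female mortality below male at all ages).
.siler_params <- list(
  female = c(a1 = 0.060, b1 = 1.15, c = 0.0022, a3 = 2.6e-5, b3 = 0.0985),
  male   = c(a1 = 0.070, b1 = 1.10, c = 0.0030, a3 = 3.6e-5, b3 = 0.0960)
)

# Internal single-year grid extends beyond the published terminal age so the
# open 80+ group's person-years can be accumulated explicitly.
.EXT_AGE_MAX <- 130L

#' Bundled standard survivorship schedule
#'
#' Returns the package's baseline survivorship column `lx` on single ages
#' 0 to 130 (radix 100000), generated from a sex-specific Siler hazard
#' (exponentially declining infant component, constant background, Gompertz
#' senescence). It is a synthetic stand-in standard for relational life-table
#' fitting, not an empirical schedule; its provenance string says so.
#'
#' @param sex `"female"` or `"male"`.
#' @param radix Starting cohort size, default 100000.
#' @return A list with `sex`, `ages`, `lx` (length 131), `radix`, `e0`
#'   (life expectancy at birth implied by the schedule) and `provenance`.
#' @export
#' @examples
#' s <- standard_schedule("female")
#' s$e0
standard_schedule <- function(sex = c("female", "male"), radix = 1e5) {
  sex <- match.arg(sex)
  p <- .siler_params[[sex]]
  ages <- 0:.EXT_AGE_MAX
  # midpoint hazard over each single-year interval
  mid <- ages[-length(ages)] + 0.5
  h <- p["a1"] * exp(-p["b1"] * mid) + p["c"] + p["a3"] * exp(p["b3"] * mid)
  lx <- radix * c(1, exp(-cumsum(h)))
  out <- list(sex = sex, ages = ages, lx = lx, radix = radix,
              provenance = paste0(
                "synthetic Siler-hazard standard (", sex, "); ",
                "not an empirical model life table"))
  out$e0 <- .e0_from_lx_ext(lx)
  class(out) <- "standard_schedule"
  out
}

# e0 from an extended single-year lx column using the same person-years
# convention as the published table: separation factor 0.3 in the first year
# of life, 0.5 afterwards.
.e0_from_lx_ext <- function(lx) {
  Lx <- .Lx_from_lx_ext(lx)
  sum(Lx) / lx[1]
}

.Lx_from_lx_ext <- function(lx, a0 = 0.3) {
  n <- length(lx)
  Lx <- 0.5 * (lx[-n] + lx[-1])
  Lx[1] <- lx[2] + a0 * (lx[1] - lx[2])  # infant deaths early in interval
  Lx
}

# Collapse an extended lx column into a published life table with an open
# terminal group at `terminal_age`.
.life_table_from_lx_ext <- function(lx_ext, sex, radix,
                                    terminal_age = TERMINAL_AGE, a0 = 0.3) {
  ages <- 0:terminal_age
  A <- terminal_age
  Lx_ext <- .Lx_from_lx_ext(lx_ext, a0 = a0)     # ages 0 .. EXT-1
  lx <- lx_ext[ages + 1]
  qx <- c(1 - lx_ext[2:(A + 1)] / lx_ext[1:A], 1)
  Lx <- c(Lx_ext[1:A], sum(Lx_ext[(A + 1):length(Lx_ext)]))
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  structure(
    data.frame(sex = sex, age = ages, qx = qx, lx = lx,
               Lx = Lx, Tx = Tx, ex = ex),
    radix = radix,
    terminal_age = A,
    lx_extended = lx_ext,
    class = c("life_table", "data.frame")
  )
}

#' Build a life table from a survivorship column
#'
#' Constructs a published life table directly from a single-year `lx`
#' vector. The vector must extend at least one age past the intended open
#' terminal group; everything above `terminal_age` is pooled into the
#' terminal person-years aggregate. Useful for toy schedules in examples
#' and for loading externally supplied survivorship columns.
#'
#' @param lx Survivorship at exact ages `0, 1, 2, ...`; strictly positive at
#'   0, non-increasing, non-negative.
#' @param sex `"female"` or `"male"` label.
#' @param terminal_age Open terminal age (default: `length(lx) - 2`, so the
#'   last element closes out the schedule).
#' @param a0 Separation factor for the first year of life (average fraction
#'   of the year lived by those dying in it); 0.3 by default, 0.5 gives
#'   fully linear person-years.
#' @return A `life_table`.
#' @export
#' @examples
#' toy <- life_table_from_lx(c(100000, 90000, 50000, 0), "female",
#'                           terminal_age = 2, a0 = 0.5)
#' survival_ratios(toy)$advance
life_table_from_lx <- function(lx, sex = c("female", "male"),
                               terminal_age = length(lx) - 2L, a0 = 0.3) {
  sex <- match.arg(sex)
  assert_numeric_finite(lx, "lx")
  assert_that(lx[1] > 0, "radix lx[1] must be positive")
  assert_that(all(diff(lx) <= 0) && all(lx >= 0),
              "`lx` must be non-increasing and non-negative")
  assert_that(terminal_age >= 1 && terminal_age <= length(lx) - 2L,
              "`terminal_age` must leave at least one age above it in `lx`")
  .life_table_from_lx_ext(lx, sex = sex, radix = lx[1],
                          terminal_age = as.integer(terminal_age), a0 = a0)
}

.logit_surv <- function(l) {
  # Brass logit of survivorship proportions l in (0, 1)
  l <- pmin(pmax(l, 1e-12), 1 - 1e-12)
  0.5 * log((1 - l) / l)
}

.lx_from_alpha <- function(alpha, standard) {
  ls <- standard$lx / standard$radix
  Y <- .logit_surv(ls[-1])                # age 0 stays at the radix
  lx <- c(1, 1 / (1 + exp(2 * (alpha + Y)))) * standard$radix
  lx
}

#' Fit a life table to a target life expectancy
#'
#' Warps the standard survivorship schedule through the Brass logit
#' relational model with slope 1, solving for the shift `alpha` so that the
#' resulting table's life expectancy at birth matches `target_e0` to within
#' 1e-6 years. The published table runs on single ages 0 to the open
#' terminal group (default 80+); person-years use a separation factor of 0.3
#' in the first year of life and 0.5 at older ages.
#'
#' @param target_e0 Target life expectancy at birth in years. Must lie in the
#'   interval attainable by shifting the standard over `alpha_bounds`
#'   (roughly 1 to 100 years for the bundled standards); an out-of-range
#'   target raises an error naming the achievable interval.
#' @param sex `"female"` or `"male"` (selects the default standard).
#' @param standard A [standard_schedule()] object; defaults to the bundled
#'   standard for `sex`.
#' @param alpha_bounds Search interval for the logit shift parameter.
#' @return A `life_table` data frame with columns `sex`, `age`, `qx`, `lx`,
#'   `Lx`, `Tx`, `ex`, and attributes `radix`, `alpha`, `lx_extended`.
#' @export
#' @examples
#' lt <- fit_life_table(70, "female")
#' life_table_e0(lt)
fit_life_table <- function(target_e0, sex = c("female", "male"),
                           standard = standard_schedule(sex),
                           alpha_bounds = c(-3.5, 3.5)) {
  sex <- match.arg(sex)
  assert_numeric_finite(target_e0, "target_e0")
  assert_that(length(target_e0) == 1L, "`target_e0` must be a single value")

  e0_of <- function(alpha) .e0_from_lx_ext(.lx_from_alpha(alpha, standard))
  lo <- e0_of(alpha_bounds[2])  # larger alpha -> higher mortality -> lower e0
  hi <- e0_of(alpha_bounds[1])
  if (target_e0 < lo || target_e0 > hi) {
    stop_dividendsim(
      "target_e0 = %.2f outside the attainable interval [%.2f, %.2f] years",
      target_e0, lo, hi, class = "dividendsim_e0_range_error")
  }
  root <- stats::uniroot(function(a) e0_of(a) - target_e0,
                         interval = alpha_bounds, tol = 1e-12)
  alpha <- root$root
  lt <- .life_table_from_lx_ext(.lx_from_alpha(alpha, standard),
                                sex = sex, radix = standard$radix)
  attr(lt, "alpha") <- alpha
  attr(lt, "beta") <- 1
  attr(lt, "standard_provenance") <- standard$provenance
  lt
}

#' Life expectancy at birth of a life table
#'
#' @param lt A `life_table`.
#' @return `T0 / l0` in years.
#' @export
life_table_e0 <- function(lt) {
  lt$Tx[1] / lt$lx[1]
}

#' Survival ratios for cohort advancement
#'
#' Converts a life table into the per-age survival proportions the
#' projection engine applies when moving a cohort from age `a - 1` to `a`
#' over one year: `S(a) = L(a) / L(a - 1)` for ages below the terminal
#' group, and for the open terminal group the ratio of person-years
#' aggregates `T(A) / T(A - 1)` (the proportion of the combined ages
#' `A - 1` and `A+` cohort surviving into `A+`). Also returns the
#' birth-to-mid-year factor `L0 / l0` used for the infant cohort.
#'
#' @param lt A `life_table`.
#' @return A list with `sex`, `advance` (named vector over ages `1..A`,
#'   entry `a` being the ratio for advancing into age `a`; entry `A` is the
#'   terminal aggregate ratio), and `infant` (`L0 / l0`). All values in
#'   (0, 1].
#' @export
survival_ratios <- function(lt) {
  assert_that(inherits(lt, "life_table"), "`lt` must be a life_table")
  A <- attr(lt, "terminal_age")
  Lx <- lt$Lx
  Tx <- lt$Tx
  if (any(Lx <= 0)) {
    stop_dividendsim("degenerate schedule: non-positive person-years at age %d",
                     lt$age[which(Lx <= 0)[1]])
  }
  adv <- Lx[2:A] / Lx[1:(A - 1)]          # advancing into ages 1..A-1
  term <- Tx[A + 1] / Tx[A]               # (A-1, A+) pooled into A+
  advance <- c(adv, term)
  names(advance) <- as.character(1:A)
  advance <- pmin(advance, 1)
  list(sex = lt$sex[1], advance = advance, infant = min(Lx[1] / lt$lx[1], 1))
}

#' Write a life table to CSV
#'
#' Columns `sex, age, qx, lx, Lx, Tx, ex`; the radix is recorded in a
#' leading `#` comment line.
#'
#' @param lt A `life_table`.
#' @param path Output file path.
#' @export
write_life_table_csv <- function(lt, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# life table; radix l0 = %g", attr(lt, "radix")), con)
  utils::write.csv(as.data.frame(lt)[, c("sex", "age", "qx", "lx",
                                         "Lx", "Tx", "ex")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table> sex=%s, ages 0..%d+ (radix %g), e0 = %.3f years\n",
              x$sex[1], attr(x, "terminal_age"), attr(x, "radix"),
              life_table_e0(x)))
  invisible(x)
}
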
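# Single-age two-sex population tables and the Beers ordinary procedure for
# disaggregating five-year census age groups into single years of age.

#' Construct a single-age two-sex population table
#'
#' The canonical population container: one calendar year of person counts on
#' single ages 0 to the open terminal group (80+ by default), by sex.
#'
#' @param year Calendar year the counts refer to (mid-year convention).
#' @param female,male Non-negative count vectors of length 81 (ages 0..80+).
#' @return An `age_sex_table`: a data frame with columns `year`, `age`,
#'   `sex`, `population`.
#' @export
#' @examples
#' tab <- age_sex_table(2001, female = rep(100, 81), male = rep(105, 81))
#' total_population(tab)
age_sex_table <- function(year, female, male) {
  n <- length(AGES)
  assert_that(length(female) == n && length(male) == n,
              "`female` and `male` must have length %d (ages 0..%d+)",
              n, TERMINAL_AGE)
  assert_numeric_finite(female, "female")
  assert_numeric_finite(male, "male")
  assert_that(all(female >= 0) && all(male >= 0),
              "population counts must be non-negative")
  structure(
    data.frame(year = as.integer(year),
               age = rep(AGES, 2L),
               sex = rep(SEXES, each = n),
               population = c(female, male)),
    class = c("age_sex_table", "data.frame")
  )
}

#' @export
print.age_sex_table <- function(x, ...) {
  cat(sprintf("<age_sex_table> year %d, ages 0..%d+, total %.0f persons\n",
              x$year[1], TERMINAL_AGE, total_population(x)))
  invisible(x)
}

#' Extract one sex's count vector, ordered by age
#'
#' @param table An `age_sex_table`.
#' @param sex `"female"` or `"male"`.
#' @return Numeric vector of length 81 named by age.
#' @export
sex_counts <- function(table, sex = c("female", "male")) {
  sex <- match.arg(sex)
  rows <- table[table$sex == sex, ]
  out <- rows$population[order(rows$age)]
  names(out) <- AGES
  out
}

#' Total population of a table
#' @param table An `age_sex_table`.
#' @return Sum of all cells.
#' @export
total_population <- function(table) sum(table$population)

# ---------------------------------------------------------------------------
# Beers ordinary interpolation
# ---------------------------------------------------------------------------

# Published Beers "ordinary" subdivision multipliers. Each panel carries the
# coefficients for the five single-year values of one five-year group as
# linear combinations of five group totals: the first/second panels use
# groups 1..5, mid panels groups (k-2)..(k+2), and the last two panels are
# the reverse-mirror of the first two. Column sums are exactly 1 for the
# panel's own group and 0 elsewhere, which is what makes the procedure
# group-sum preserving.
.beers_first <- matrix(c(
   0.3333, -0.1636, -0.0210,  0.0796, -0.0283,
   0.2595, -0.0780,  0.0130,  0.0100, -0.0045,
   0.1924,  0.0064,  0.0184, -0.0256,  0.0084,
   0.1329,  0.0844,  0.0054, -0.0356,  0.0129,
   0.0819,  0.1508, -0.0158, -0.0284,  0.0115
), nrow = 5, byrow = TRUE)

.beers_second <- matrix(c(
   0.0404,  0.2000, -0.0344, -0.0128,  0.0068,
   0.0093,  0.2268, -0.0402,  0.0028,  0.0013,
  -0.0108,  0.2272, -0.0248,  0.0112, -0.0028,
  -0.0198,  0.1992,  0.0172,  0.0072, -0.0038,
  -0.0191,  0.1468,  0.0822, -0.0084, -0.0015
), nrow = 5, byrow = TRUE)

.beers_mid <- matrix(c(
  -0.0117,  0.0804,  0.1570, -0.0284,  0.0027,
  -0.0020,  0.0160,  0.2200, -0.0400,  0.0060,
   0.0050, -0.0280,  0.2460, -0.0280,  0.0050,
   0.0060, -0.0400,  0.2200,  0.0160, -0.0020,
   0.0027, -0.0284,  0.1570,  0.0804, -0.0117
), nrow = 5, byrow = TRUE)

# reverse-mirror: last panels read the first panels backwards
.beers_penult <- .beers_second[5:1, 5:1]
.beers_last   <- .beers_first[5:1, 5:1]

#' Split five-year age-group totals into single ages (Beers ordinary)
#'
#' Applies the published Beers ordinary interpolation multipliers to a
#' vector of consecutive five-year group totals, producing five single-age
#' values per group that sum exactly to the group total. The procedure is
#' linear in its input; should the polynomial panels produce a negative
#' single-age value (possible for sharply irregular inputs), it is floored
#' at zero and the group's mass redistributed proportionally over the
#' remaining ages, preserving the group sum, with a warning.
#'
#' @param group_totals Numeric vector of at least 5 consecutive five-year
#'   group totals, all non-negative.
#' @return Numeric vector of length `5 * length(group_totals)` of single-age
#'   values.
#' @export
#' @examples
#' x <- beers_split(c(100, 120, 140, 130, 110, 90, 70, 50))
#' sum(x[1:5])  # 100, the first group total
beers_split <- function(group_totals) {
  assert_numeric_finite(group_totals, "group_totals")
  n <- length(group_totals)
  assert_that(n >= 5, paste0(
    "Beers ordinary needs at least 5 consecutive five-year groups ",
    "(two boundary panels each side plus one interior); got %d"), n)
  assert_that(all(group_totals >= 0), "group totals must be non-negative")

  out <- numeric(5 * n)
  panel_vals <- function(coef, groups) as.vector(coef %*% groups)
  out[1:5]   <- panel_vals(.beers_first,  group_totals[1:5])
  out[6:10]  <- panel_vals(.beers_second, group_totals[1:5])
  if (n > 4) {
    for (k in 3:(n - 2)) {
      out[(5 * k - 4):(5 * k)] <-
        panel_vals(.beers_mid, group_totals[(k - 2):(k + 2)])
    }
  }
  out[(5 * n - 9):(5 * n - 5)] <-
    panel_vals(.beers_penult, group_totals[(n - 4):n])
  out[(5 * n - 4):(5 * n)] <-
    panel_vals(.beers_last, group_totals[(n - 4):n])

  if (any(out < 0)) {
    warning("Beers split produced negative single-age values; ",
            "floored at 0 and redistributed within their groups")
    for (k in seq_len(n)) {
      idx <- (5 * k - 4):(5 * k)
      v <- out[idx]
      if (any(v < 0)) {
        v <- pmax(v, 0)
        s <- sum(v)
        out[idx] <- if (s > 0) v * (group_totals[k] / s)
                    else rep(group_totals[k] / 5, 5)
      }
    }
  }
  out
}

# ---------------------------------------------------------------------------
# Band aggregation
# ---------------------------------------------------------------------------

#' Aggregate a population table over closed age bands
#'
#' @param table An `age_sex_table`.
#' @param bands A list of `c(lo, hi)` closed integer age bands that must
#'   partition 0..80+ (80 stands for the open group). Default: the dependency
#'   bands 0-14, 15-64, 65+.
#' @return A named numeric vector of band totals (persons, both sexes); the
#'   names are `"lo-hi"`. Band totals sum to the table total.
#' @export
#' @examples
#' tab <- age_sex_table(2001, rep(10, 81), rep(10, 81))
#' aggregate_bands(tab)
aggregate_bands <- function(table,
                            bands = list(c(0, 14), c(15, 64),
                                         c(65, TERMINAL_AGE))) {
  assert_that(length(bands) >= 1, "at least one band required")
  covered <- unlist(lapply(bands, function(b) {
    assert_that(length(b) == 2 && b[1] <= b[2], "bands must be c(lo, hi)")
    b[1]:b[2]
  }))
  assert_that(!anyDuplicated(covered) && setequal(covered, AGES),
              "bands must partition ages 0..%d+ without overlap",
              TERMINAL_AGE)
  out <- vapply(bands, function(b) {
    sum(table$population[table$age >= b[1] & table$age <= b[2]])
  }, numeric(1))
  names(out) <- vapply(bands, function(b) paste0(b[1], "-", b[2]),
                       character(1))
  out
}

# ---------------------------------------------------------------------------
# CSV I/O
# ---------------------------------------------------------------------------

#' Read a population table from CSV
#'
#' Strict schema: columns `year, age, sex, population`; `age` is an integer
#' single year with 80 denoting the open 80+ group; `sex` is `F`/`M` (or
#' `female`/`male`); UTF-8, comma-separated, `.` decimal.
#'
#' @param path CSV file path.
#' @return An `age_sex_table`.
#' @export
read_age_sex_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("year", "age", "sex", "population")
  assert_that(all(need %in% names(df)),
              "CSV must have columns: %s", paste(need, collapse = ", "))
  sx <- tolower(as.character(df$sex))
  sx[sx == "f"] <- "female"
  sx[sx == "m"] <- "male"
  assert_that(all(sx %in% SEXES), "sex column must be F/M or female/male")
  df$sex <- sx
  assert_that(length(unique(df$year)) == 1L,
              "population CSV must contain a single year")
  f <- df[df$sex == "female", ]
  m <- df[df$sex == "male", ]
  assert_that(setequal(f$age, AGES) && setequal(m$age, AGES),
              "each sex must cover every single age 0..%d exactly once",
              TERMINAL_AGE)
  age_sex_table(df$year[1],
                female = f$population[order(f$age)],
                male = m$population[order(m$age)])
}

#' Write a population table (or several years of them) to CSV
#'
#' @param tables An `age_sex_table` or a list of them.
#' @param path Output path.
#' @param scenario Optional scenario id column.
#' @export
write_age_sex_csv <- function(tables, path, scenario = NULL) {
  if (inherits(tables, "age_sex_table")) tables <- list(tables)
  df <- do.call(rbind, lapply(tables, as.data.frame))
  if (!is.null(scenario)) df <- cbind(scenario = scenario, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
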
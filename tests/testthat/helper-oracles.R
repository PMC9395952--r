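# Independent oracle implementations used across the suite. Each is a
# deliberately separate computation path from the package internals:
# closed forms, brute-force scans, and direct matrix algebra.

# --- Leslie-matrix single-step oracle -------------------------------------
# Survival-only projection matrix on ages 0..A (A open terminal): entry for
# destination age a is the mean interval survival ratio; the terminal row
# pools ages A-1 and A+. Fertility row left at zero (births are handled by
# a separate operation in the engine).
leslie_matrix <- function(s_mean) {
  A <- length(s_mean)
  M <- matrix(0, A + 1, A + 1)
  for (a in 1:(A - 1)) M[a + 1, a] <- s_mean[a]
  M[A + 1, A] <- s_mean[A]
  M[A + 1, A + 1] <- s_mean[A]
  M
}

# --- trapezoidal life-expectancy oracle -----------------------------------
# e0 from a pure survivorship column by trapezoidal integration; no
# separation factors, no person-years columns from the package.
e0_trapezoid <- function(lx) {
  sum(0.5 * (lx[-1] + lx[-length(lx)])) / lx[1]
}

# --- Beers ordinary coefficient-table oracle ------------------------------
# Assembles the full (5n x n) subdivision operator row by row from the
# published multiplier panels and applies it as one matrix-vector product.
beers_operator <- function(n) {
  stopifnot(n >= 5)
  first <- rbind(
    c( 0.3333, -0.1636, -0.0210,  0.0796, -0.0283),
    c( 0.2595, -0.0780,  0.0130,  0.0100, -0.0045),
    c( 0.1924,  0.0064,  0.0184, -0.0256,  0.0084),
    c( 0.1329,  0.0844,  0.0054, -0.0356,  0.0129),
    c( 0.0819,  0.1508, -0.0158, -0.0284,  0.0115))
  second <- rbind(
    c( 0.0404,  0.2000, -0.0344, -0.0128,  0.0068),
    c( 0.0093,  0.2268, -0.0402,  0.0028,  0.0013),
    c(-0.0108,  0.2272, -0.0248,  0.0112, -0.0028),
    c(-0.0198,  0.1992,  0.0172,  0.0072, -0.0038),
    c(-0.0191,  0.1468,  0.0822, -0.0084, -0.0015))
  mid <- rbind(
    c(-0.0117,  0.0804,  0.1570, -0.0284,  0.0027),
    c(-0.0020,  0.0160,  0.2200, -0.0400,  0.0060),
    c( 0.0050, -0.0280,  0.2460, -0.0280,  0.0050),
    c( 0.0060, -0.0400,  0.2200,  0.0160, -0.0020),
    c( 0.0027, -0.0284,  0.1570,  0.0804, -0.0117))
  B <- matrix(0, 5 * n, n)
  B[1:5, 1:5] <- first
  B[6:10, 1:5] <- second
  for (k in 3:(n - 2)) B[(5 * k - 4):(5 * k), (k - 2):(k + 2)] <- mid
  B[(5 * n - 9):(5 * n - 5), (n - 4):n] <- second[5:1, 5:1]
  B[(5 * n - 4):(5 * n), (n - 4):n] <- first[5:1, 5:1]
  B
}

# --- exhaustive window-of-opportunity scan --------------------------------
window_scan <- function(year, share_child, share_old, dep_total) {
  ok_years <- year[share_child < 0.30 & share_old < 0.15]
  if (length(ok_years) == 0) return(list(open = NA, eff_close = NA))
  open <- ok_years[1]
  best <- Inf; eff <- NA
  for (i in seq_along(year)) {
    if (dep_total[i] < best) { best <- dep_total[i]; eff <- year[i] }
  }
  list(open = open, eff_close = eff)
}

# --- shared fixtures ------------------------------------------------------
# small toy life table with linear person-years, hand-computable
toy_lt <- function() {
  life_table_from_lx(c(100000, 90000, 50000, 0), "female",
                     terminal_age = 2, a0 = 0.5)
}

# a constant-rate scenario over a short horizon, for engine tests
const_scenario <- function(tfr = 3.14, srb = 111, e0_f = 63.9, e0_m = 62.3,
                           start = 2001, end = 2031) {
  inputs <- default_inputs(start, end)
  inputs$base <- list(tfr = tfr, srb = srb, e0_f = e0_f, e0_m = e0_m,
                      dist_mode = 25, dist_spread = 5.5)
  build_as_usual(inputs)
}
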
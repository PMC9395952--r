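# Internal validation helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dividendsim <- function(msg, ..., class = "dividendsim_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop_dividendsim(msg, ...)
  invisible(TRUE)
}

assert_numeric_finite <- function(x, name) {
  assert_that(is.numeric(x) && all(is.finite(x)),
              "`%s` must be numeric and finite", name)
}

SEXES <- c("female", "male")

# Default age grid: single years 0..80 with 80 open-ended (80+).
TERMINAL_AGE <- 80L
AGES <- 0:80
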
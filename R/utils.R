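## Internal helpers shared across modules.

## Gas constant in calorie units, matching the cal-based heat capacity scale.
.R_GAS <- 1.987  # cal / (mol K)

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code does not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

## Deterministic per-unit substream seed derived from a master seed, so
## cohorts are reproducible under subsetting.  Kept below 2^31 - 1.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(index)) %%
    .Machine$integer.max)
}

## Trapezoidal integral on an arbitrary strictly increasing grid.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
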
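## Internal helpers shared across modules.

# Classed errors so callers can condition on failure mode.
stop_pl <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, ..., class = c(class, "plgicomp_error", "error", "condition")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

is_count <- function(x, min = 0L) {
  is_scalar_number(x) && x >= min && x == as.integer(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the random-number generator seeded to `seed`, then
#' restores whatever RNG state (if any) existed before the call. All
#' randomness in the package flows through this helper, so no function
#' leaves a footprint on the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is_count(seed)) stop_pl("'seed' must be a single integer", "pl_domain_error")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Log-spaced competitor concentration grid
#'
#' Builds the default titration grid used throughout: `n` log-spaced
#' concentrations between `from` and `to`, optionally preceded by an exact
#' zero point that anchors the normalization of competition curves.
#'
#' @param from,to Positive concentrations (molar) spanning the titration.
#' @param n Number of log-spaced points (default 17).
#' @param include_zero Prepend a zero-competitor point? Default `TRUE`.
#' @return Numeric vector of concentrations in molar, increasing.
#' @export
#' @examples
#' default_competitor_grid(1e-11, 1e-6)
default_competitor_grid <- function(from, to, n = 17L, include_zero = TRUE) {
  if (!is_scalar_number(from) || !is_scalar_number(to) || from <= 0 || to <= from) {
    stop_pl("need 0 < from < to", "pl_domain_error")
  }
  if (!is_count(n, min = 2L)) stop_pl("'n' must be an integer >= 2", "pl_domain_error")
  g <- 10^seq(log10(from), log10(to), length.out = n)
  if (include_zero) c(0, g) else g
}

# Unit handling for config files: concentrations are molar internally.
.unit_factors <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9, pM = 1e-12)

to_molar <- function(x, units = "M") {
  f <- .unit_factors[[units]]
  if (is.null(f)) stop_pl(sprintf("unknown concentration unit '%s'", units), "pl_format_error")
  x * f
}
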
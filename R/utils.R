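#' Round half away from zero
#'
#' Report-table rounding convention. Unlike [base::round()] (banker's
#' rounding), ties go away from zero: `round_half_up(0.125, 2)` is 0.13.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (may be negative).
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Round to the nearest 10
#'
#' Convention used for reported ribosome totals and densities, which are
#' printed as multiples of 10.
#'
#' @param x numeric vector.
#' @return `x` rounded half-away-from-zero to the nearest multiple of 10.
#' @export
round_to_10 <- function(x) round_half_up(x, digits = -1)

# Run `expr` under a local, seeded RNG stream without disturbing the
# caller's RNG state. seed = NULL leaves the global stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= lower) {
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  }
  if (!strict && x < lower) {
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  }
  invisible(x)
}

match_choice <- function(arg, choices) {
  match.arg(arg, choices)
}
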
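## internal helpers shared across modules

#' Evaluate code with a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG state so
#' seeded package functions do not disturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## parameter-check helper: stops with the violated condition spelled out
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## trim + drop empties; optional uppercase normalization for human symbols
clean_symbols <- function(x, normalize_case = FALSE) {
  x <- trimws(as.character(x))
  x <- x[nzchar(x) & !is.na(x)]
  if (normalize_case) x <- toupper(x)
  x
}
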
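#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the prior
#' RNG state, so that simulation functions are reproducible without leaving a
#' footprint on the caller's random stream.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# single-field scalar checks used by configuration validators; errors name the
# offending field so callers can fix their configs directly
check_scalar <- function(x, field, type = c("count", "positive", "nonneg", "real"),
                         allow_zero = TRUE) {
  type <- match.arg(type)
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("configuration error: '%s' must be a single finite number", field),
         call. = FALSE)
  }
  switch(type,
    count = if (x < 0 || x != trunc(x)) {
      stop(sprintf("configuration error: '%s' must be a non-negative integer", field),
           call. = FALSE)
    },
    positive = if (x <= 0) {
      stop(sprintf("configuration error: '%s' must be > 0", field), call. = FALSE)
    },
    nonneg = if (x < 0) {
      stop(sprintf("configuration error: '%s' must be >= 0", field), call. = FALSE)
    },
    real = invisible(NULL)
  )
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
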
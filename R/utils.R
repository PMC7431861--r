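# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded at `seed` and restores the caller's RNG
#' state afterwards, so seeded generators do not perturb the session stream.
#' A `NULL` seed evaluates `expr` against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialise .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Accumulate validation failures and report them all at once.
check_that <- function(errors, ok, msg) {
  if (!isTRUE(ok)) errors <- c(errors, msg)
  errors
}

stop_if_errors <- function(errors, context) {
  if (length(errors)) {
    stop(context, ":\n  - ", paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

is_number <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)

is_proportion <- function(x) is_number(x) && x >= 0 && x <= 1

is_flag <- function(x) length(x) == 1L && is.logical(x) && !is.na(x)
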
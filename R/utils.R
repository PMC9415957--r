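#' Run an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' seeded helpers never perturb an enclosing simulation. A `NULL` seed leaves
#' the RNG stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a RNG state to restore
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# argument checking -----------------------------------------------------

assert_finite_numeric <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name = deparse(substitute(x)), min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != floor(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
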
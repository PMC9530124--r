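#' @useDynLib treemort, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats plogis qlogis runif rnorm rlnorm rbinom quantile var cor
#'   median predict fisher.test sd setNames aggregate
#' @importFrom utils head read.csv write.csv packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current RNG state, seeds, evaluates, and restores the state, so
#' seeded internals do not perturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to leave the stream untouched.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Fan a root seed out into named per-stage seeds (all < 2^31).
fan_seeds <- function(root_seed, stages) {
  with_seed(root_seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(stages))
    stats::setNames(as.integer(s), stages)
  })
}

sigmoid <- function(x) stats::plogis(x)

stop_tm <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_tm(sprintf("'%s' must be a finite scalar number", name))
  invisible(x)
}
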
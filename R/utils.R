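# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is_number(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g", name, lower)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g", name, lower)
  if (x > upper)
    stopf("`%s` must be <= %g", name, upper)
  invisible(x)
}

# deterministic sub-seed derivation; keeps results independent across
# stages while reproducible from one top-level seed (always < 2^31)
sub_seed <- function(seed, k) {
  v <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(k) * 7919
  as.integer(v %% 2147483647)  # exact: v < 2^53
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Standard error of the mean
#'
#' @param x numeric vector with at least two values.
#' @return `sd(x)/sqrt(length(x))`.
#' @export
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
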
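## internal helpers shared across modules

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.assertNumericVector <- function(x, name, allowNegative = TRUE) {
  if (!is.numeric(x) || anyNA(x))
    stop(sprintf("'%s' must be a numeric vector without NA", name), call. = FALSE)
  if (!allowNegative && any(x < 0))
    stop(sprintf("'%s' must be nonnegative", name), call. = FALSE)
  invisible(TRUE)
}

.assertSameLength <- function(a, b, na, nb) {
  if (length(a) != length(b))
    stop(sprintf("'%s' (length %d) and '%s' (length %d) must be aligned",
                 na, length(a), nb, length(b)), call. = FALSE)
  invisible(TRUE)
}

## population standard deviation (divisor n)
.popSd <- function(x) sqrt(mean((x - mean(x))^2))
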
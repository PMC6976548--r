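# Internal helpers shared across modules.

hazext_error <- function(message, class, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "hazext_error"),
                      call = call))
}

# Run `code` under a fixed RNG state without disturbing the caller's stream.
# `seed = NULL` leaves the current stream untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  lo <- x <= 18
  out[lo] <- log1p(exp(x[lo]))
  mid <- x > 18 & x <= 33.3
  out[mid] <- x[mid] + exp(-x[mid])
  out
}

assert_number <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  if (!ok)
    hazext_error(sprintf("`%s` must be a finite number %s %g", name,
                         if (strict) ">" else ">=", lower),
                 "hazext_domain_error")
  invisible(x)
}
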
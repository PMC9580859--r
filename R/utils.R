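# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# round-half-up to `digits` decimals; base round() rounds half to even,
# which would print 0.25 -> 0.2 where reported tables use 0.3
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < min || (!allow_zero && x == min))
    stopf("'%s' must be %s %s", name, if (allow_zero) ">=" else ">", min)
  invisible(x)
}

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's stream afterwards so fixture generation never perturbs it
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
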
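## Internal helpers: argument checking and seeded RNG scoping.

stop_glyx <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "glyx_error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_glyx(sprintf("'%s' must be a single positive finite number", name),
              "glyx_invalid_parameter")
  x
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop_glyx(sprintf("'%s' must be a single non-negative finite number", name),
              "glyx_invalid_parameter")
  x
}

## Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
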
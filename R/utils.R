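## Internal helpers: localized seeding and deterministic seed derivation.

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's RNG
# stream. seed = NULL means "use the current stream as-is".
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit hash of arbitrary scalar components, used so that any
# single cell of the benchmark grid (permutation x mechanism x rate) can be
# replayed independently of the rest of the run.
derive_seed <- function(...) {
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = ":")
  codes <- utf8ToInt(key)
  h <- 5381
  for (v in codes) h <- (h * 33 + v) %% 2147483647
  as.integer(h)
}

# Shared argument checks ------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  ok_up <- if (strict_upper) x < upper else x <= upper
  if (!ok_low || !ok_up) {
    stop(sprintf("`%s` = %s is outside its valid range", name, format(x)),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  assert_scalar_number(x, name, lower = min)
  if (x != as.integer(x)) {
    stop(sprintf("`%s` must be a whole number", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
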
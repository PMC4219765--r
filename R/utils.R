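`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state.
# Seeds passed through the package are kept as plain integers (< 2^31).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (finite && !is.finite(x)) {
    stop(sprintf("`%s` must be finite, got %s", name, format(x)), call. = FALSE)
  }
  invisible(x)
}

match_sex <- function(sex) {
  match.arg(tolower(as.character(sex)), c("male", "female"))
}
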
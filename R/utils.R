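#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (if (allow_zero) x < 0 else x <= 0)) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (allow_zero) "non-negative" else "positive"), call. = FALSE)
  }
  invisible(x)
}

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
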
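#' @keywords internal
"_PACKAGE"

## Internal assertion helper: stop() with the caller-supplied message.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Derive a stream of child seeds from one master seed so that a dataset of
## n observations is fully determined by (seed, n).  Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1L, is.finite(seed), n >= 1L)
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483629L
}

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

is_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
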
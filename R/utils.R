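# internal helpers shared across modules

# Per-class held-out count: the training side is round((1 - f) * n) under
# R's round() (half-to-even at exact midpoints) and the test side the
# remainder. This is the convention that reproduces the reference corpus's
# published per-class balanced training counts on all 39 classes; see the
# methods vignette.
split_test_count <- function(n, test_fraction) {
  n - round((1 - test_fraction) * n)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so seeded operations compose predictably.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed
#'
#' One master seed is fanned out to every pipeline stage by hashing the
#' stage label, so any stage can be re-run in isolation with exactly the
#' randomness it saw inside the full run. Results stay below `2^31 - 1`
#' (R integers are 32-bit).
#'
#' @param seed integer master seed.
#' @param stage stage label, e.g. `"balance"` or `"train:rf"`.
#' @return A derived integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
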
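# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic substream seed for unit i under a base seed. Keeps every
# derived seed in [1, 2^31 - 2] so set.seed() accepts it; adding units never
# perturbs the substreams of earlier units.
substream_seed <- function(seed, i) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(seed) %% m) * 48271 %% m
  as.integer((s + as.double(i) * 1013904223) %% (m - 1)) + 1L
}

# Draw one seed to anchor a run when the user supplied none, consuming the
# ambient RNG stream so repeated calls differ.
draw_seed <- function() {
  sample.int(2147483646L, 1L)
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == round(x)
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
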
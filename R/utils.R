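# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# random stream. All user-facing generators route their randomness through
# this, so a root seed makes every stage independently reproducible.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# Documented sub-stream offsets: one root seed drives every generator of a
# synthetic study, each stage at root + offset so stages can be re-run alone.
seed_offsets <- c(tree = 1L, communities = 2L, soil = 3L, traits = 4L,
                  permutation = 5L, ncm = 6L)

substream_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + seed_offsets[[stage]]) %% .Machine$integer.max
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
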
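# Named pseudo-random streams: each pipeline stage draws from its own
# sub-seed derived from (seed, stream name), so stages are independently
# reproducible and reordering one stage does not perturb another.

stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  # double arithmetic below 2^53, reduced to a valid 32-bit integer seed
  as.integer((abs(as.numeric(seed)) %% 1e9 * 1103 + h * 12347) %% 2147483647)
}

# Evaluate `expr` under a seeded RNG state, restoring the caller's state.
with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, stream))
  expr
}
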
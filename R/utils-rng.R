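# Hierarchical RNG streams (L'Ecuyer-CMRG) so that a single integer seed
# yields independent, order-invariant substreams: one per synthetic generator
# and one per walker. Stream k is reproducible regardless of whether streams
# 1..k-1 were ever consumed.

get_rand_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
}

set_rand_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(state)
}

# n consecutive L'Ecuyer-CMRG streams derived from `seed`
rng_streams <- function(seed, n) {
  old <- get_rand_state()
  on.exit(set_rand_state(old), add = TRUE)
  suppressWarnings(RNGkind("L'Ecuyer-CMRG"))
  set.seed(as.integer(seed))
  s <- get_rand_state()
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

# evaluate `code` with the RNG positioned at `stream`; returns list(value,
# stream = advanced stream) so a caller can thread a stream through calls
eval_with_stream <- function(stream, code) {
  old <- get_rand_state()
  on.exit(set_rand_state(old), add = TRUE)
  set_rand_state(stream)
  value <- force(code)
  list(value = value, stream = get_rand_state())
}

# run `code` under set.seed(seed) (default Mersenne-Twister), restoring the
# caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- get_rand_state()
  on.exit(set_rand_state(old), add = TRUE)
  suppressWarnings(RNGkind("Mersenne-Twister"))
  set.seed(as.integer(seed))
  force(code)
}
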
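# Deterministic per-hospital substream seeds: a 31-bit LCG-style mix of the
# master seed, the hospital index, and a purpose tag, so that adding a
# hospital (or changing what another hospital draws) never perturbs the
# stream of an existing one.
hospital_seed <- function(master_seed, index, purpose = 0L) {
  m <- 2147483629
  s <- (as.double(master_seed) %% m)
  s <- (s * 48271 + as.double(index) * 16807 + as.double(purpose) * 69621) %% m
  as.integer(s) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

sample_levels <- function(n, freq) {
  sample(names(freq), n, replace = TRUE, prob = freq)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
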
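# run expr under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  eval.parent(substitute(expr))
}

# deterministic member seed from (base seed, donor id, index); stays < 2^31
# and is stable under adding donors or members elsewhere
derive_seed <- function(base_seed, donor_id, index) {
  h <- as.double(base_seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(donor_id)))
    h <- (h * 31 + ch) %% 2147483647
  h <- (h * 131 + as.double(index)) %% 2147483647
  as.integer(h) + 1L
}
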
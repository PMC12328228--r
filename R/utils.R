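# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive an independent child seed from a root seed and one or two stream
# indices, keeping the result a valid positive 32-bit integer. Multiplicative
# hashing keeps nearby (seed, index) pairs well separated.
mix_seed <- function(seed, i, j = 0L) {
  m <- 2147483629 # large prime < 2^31
  s <- (as.numeric(seed) %% m)
  s <- (s * 48271 + as.numeric(i) * 16807 + as.numeric(j) * 69621 + 1) %% m
  s <- (s * 48271 + 12345) %% m
  as.integer(s + 1)
}

# scene-by-overpass label used as the blocking unit throughout
sxo_id <- function(scene_id, overpass_id) {
  paste(scene_id, overpass_id, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
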
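# Internal helpers shared across modules.

# Evaluate `code` under a given RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialize RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

# Phred+33 encoding of integer quality scores (capped at 93).
phred_encode <- function(q) {
  rawToChar(as.raw(pmin(as.integer(q), 93L) + 33L))
}

# Integer quality scores from a phred+33 string (vector of ints).
phred_decode <- function(s) {
  as.integer(charToRaw(s)) - 33L
}

# Short hexadecimal fingerprint of an R object (polynomial rolling hash over
# its deparse); identifies a configuration in output headers, not a
# cryptographic hash.
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 17
  for (b in bytes) {
    h <- (h * 131 + b) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
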
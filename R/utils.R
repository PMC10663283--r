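# Internal helpers: scoped RNG and a small stable hash for provenance.

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards, so seeded operations are pure functions of their inputs.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a over the UTF-8 bytes of a string, in exact double arithmetic
# (products stay below 2^56).  Returns an 8-hex-digit string.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(s, collapse = "\x1f"))))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h <- (h * 16777619) %% 4294967296
  }
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

# Deterministic derivation of per-stage RNG seeds from one root seed.
# seed = FNV-1a("root|delta|stage") reduced to a positive 31-bit integer.
derive_seed <- function(root_seed, delta, stage) {
  hx <- fnv1a32(sprintf("%d|%.10g|%s", as.integer(root_seed),
                        as.numeric(delta), as.character(stage)))
  as.integer(strtoi(substr(hx, 1, 7), 16L) %% 2147483647L + 1L)
}

# Stable hash of run inputs (model, task, grid, ...) used to tie stores to
# their originating configuration.  Arguments are reduced to plain lists and
# serialized to JSON at 12 significant digits before hashing.
config_fingerprint <- function(...) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  ser <- vapply(list(...), function(p) {
    as.character(jsonlite::toJSON(strip(p), digits = 12, auto_unbox = TRUE))
  }, character(1))
  fnv1a32(paste(ser, collapse = "\x1e"))
}
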
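# Internal helpers shared across modules.

# Run `expr` under a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds (< 2^31) from one integer seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)

# CRC-32 (PNG/zip polynomial). Works on raw vectors; returns a signed 32-bit
# integer holding the unsigned bit pattern.
.crc_table <- local({
  tab <- integer(256)
  for (k in 0:255) {
    cc <- k
    for (i in 1:8) {
      cc <- if (bitwAnd(cc, 1L)) bitwXor(bitwShiftR(cc, 1L), -306674912L) else bitwShiftR(cc, 1L)
    }
    tab[k + 1L] <- cc
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (x in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), .crc_table[bitwAnd(bitwXor(crc, x), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}
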
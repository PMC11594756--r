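# Internal helpers shared across modules.

# Time is stored in seconds; window arithmetic is done in milliseconds on a
# 0.01 ms grid so boundary comparisons are deterministic.
MS_RES <- 0.01

.to_ms <- function(t_s) round(t_s * 1000, 2)

# Evaluate `expr` under `seed` without clobbering the caller's RNG stream.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic 31-based string/integer hash onto [1, 2^31 - 2]; used to derive
# per-recording seeds from (master_seed, group, DIV, replicate). All arithmetic
# stays below 2^53 so the result is exact in double precision.
.derive_seed <- function(master_seed, group, div, replicate) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (ch in utf8ToInt(as.character(group))) h <- (h * 31 + ch) %% m
  h <- (h * 31 + as.numeric(div)) %% m
  h <- (h * 31 + as.numeric(replicate)) %% m
  as.integer(h) + 1L
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Multiplication is split into 16-bit halves to stay within exact doubles.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256                      # XOR with a byte only touches the low 8 bits
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Stable hash of an R object (via its JSON serialisation) used to stamp
# pipeline output tables.
.params_hash <- function(x) {
  .fnv1a(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, null = "null",
                          force = TRUE))
}

.write_table_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# meanet params_hash=%s", hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}
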
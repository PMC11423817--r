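# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Unique track key across kymographs (track_id is only unique per kymograph).
track_key <- function(df) paste(df$kymograph_id, df$track_id, sep = "\r")

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    stop_config("'%s' must be > 0 (got %g)", name, x)
  invisible(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_config("'%s' must be probabilities in [0, 1]", name)
  invisible(x)
}

# 32-bit FNV-1a hash of a character scalar; used to stamp outputs with a
# reproducible configuration fingerprint without a binary dependency.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(paste(s, collapse = "\n"))))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # multiply mod 2^32 without exceeding double precision
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Track key including condition (for calibrated, possibly multi-condition
# collections where kymograph ids can repeat across conditions).
ctrack_key <- function(df)
  paste(df$condition, df$kymograph_id, df$track_id, sep = "\r")

# stable row order helper
order_by <- function(df, cols) {
  do.call(order, c(unname(df[cols]), list(method = "radix")))
}
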
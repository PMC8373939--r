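# Internal helpers shared across modules.

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-pathway RNG substreams so results do not depend on the order in which
# pathways are evaluated. Arithmetic stays below 2^53 so doubles are exact.
.hash_string <- function(x) {
  m <- 2147483629
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% m
  h
}

# Combine a user seed with a pathway id into a substream seed < 2^31.
.substream_seed <- function(seed, id) {
  m <- 2147483629
  as.integer((.hash_string(id) + (as.double(seed) %% m) * 10007) %% m)
}

# Sort gene ids lexicographically in a locale-independent way.
.lex_order <- function(...) order(..., method = "radix")

.msg <- function(..., quiet = FALSE) {
  if (!quiet) message(...)
  invisible(NULL)
}

# Fixed-format numeric serialization used by all table/JSON writers so that
# repeated runs are byte-identical across platforms.
.fmt_num <- function(x, digits = 6) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(v, digits = digits, format = "g")
  }, character(1))
  out
}

# Clamp a p-value away from 0/1 before converting to a normal quantile.
.clamp_p <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)
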
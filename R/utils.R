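# Internal helpers shared across modules.

# Polynomial string hash onto [0, 1e9+7). Used to derive deterministic
# per-record RNG streams and fingerprint identifiers; arithmetic stays
# below 2^53 so the result is exact in doubles.
.HASH_P <- 1000000007

.str_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% .HASH_P
  h
}

.hash_combine <- function(h, x) {
  (h * 1000003 + x) %% .HASH_P
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
.with_local_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Case-insensitive, whitespace-normalized key used wherever target names
# define identity (redundancy groups, intersections).
.norm_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

.stop_ivs <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "ivs_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}
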
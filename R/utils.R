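## Internal helpers: classed conditions and seed hygiene.

stop_classed <- function(class, msg, call. = FALSE) {
  cnd <- structure(
    class = c(class, "stresshrv_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cnd)
}

stop_format <- function(msg) stop_classed("stresshrv_format_error", msg)
stop_config <- function(msg) stop_classed("stresshrv_config_error", msg)
stop_state  <- function(msg) stop_classed("stresshrv_state_error", msg)
stop_domain <- function(msg) stop_classed("stresshrv_domain_error", msg)

## Evaluate `expr` under a local RNG stream seeded with `seed`, restoring
## the caller's .Random.seed afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_config("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a master seed; stays below 2^31 - 1.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master)
  for (i in idx) s <- (s * 69069 + 12345 + i) %% 2147483629
  as.integer(s)
}

## FNV-1a hash of a character scalar, as 8 hex digits (manifest fingerprints).
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483648), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
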
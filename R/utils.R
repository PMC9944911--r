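# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-run seed derived from a master seed and a run index,
# kept inside the 32-bit integer range.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) %% 65011 + 1) * 30011 +
               as.numeric(index) * 7919) %% 2147483629L
}

#' Hash a configuration object
#'
#' Stable FNV-1a hash of the serialized object, used to stamp generated
#' artifacts (trees, cohorts, maps) with the configuration that produced them.
#'
#' @param x Any serializable R object.
#' @return A 8-character hexadecimal string.
#' @export
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b + 1) %% 2147483629
  sprintf("%08x", as.integer(h))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
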
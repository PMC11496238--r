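`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  code
}

# Cheap deterministic content hash (FNV-1a over the formatted fields) used
# to stamp harmonized pairs so reports can assert that all estimators saw
# identical inputs. Not cryptographic.
content_hash <- function(...) {
  txt <- paste(unlist(lapply(list(...), format, digits = 15)), collapse = "|")
  bytes <- utf8ToInt(txt)
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Derive a per-component child seed from a master seed
#'
#' One global seed expands to deterministic per-stage seeds via a counter
#' scheme, so any pipeline or simulation stage is independently
#' reproducible. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param offset non-negative integer counter identifying the stage.
#' @return an integer seed.
#' @export
child_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), is.numeric(offset))
  as.integer((as.double(seed) * 48271 + as.double(offset) * 1013904223) %% 2147483647)
}
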
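# Internal helpers: deterministic RNG streams and small numeric utilities.

.datatable.aware <- TRUE

#' @keywords internal
#' @noRd
clamp01 <- function(x) pmin(1, pmax(0, x))

# Derive a reproducible sub-seed from a user seed and an operation tag so
# that pipeline stages draw from independent streams but remain reproducible
# stage-by-stage. Kept below 2^31 - 1 (R integer range).
#' @keywords internal
#' @noRd
stream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(as.character(tag))) h <- (h * 31 + k) %% 1048573
  as.integer(((abs(seed) %% 1e6) * 1048583 + h * 7919 + 17) %% 2147483629) + 1L
}

# Evaluate expr with a derived seed; the caller's RNG state is untouched.
#' @keywords internal
#' @noRd
with_stream <- function(seed, tag, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, tag))
  force(expr)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
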
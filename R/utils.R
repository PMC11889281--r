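#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with a caller-located message.
stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Simulation stages (founder sampling, meiosis, effect draws, residual
#' noise, ...) each draw their own seed from the master seed and a stream
#' name, so that one stage can be re-run in isolation without disturbing
#' the others. The derivation is a small deterministic integer hash of the
#' stream name folded into the master seed, kept strictly below 2^31.
#'
#' @param seed Integer master seed.
#' @param stream Character scalar naming the sub-stream.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, "founders")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483629 + 1)
}

# Run expr with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
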
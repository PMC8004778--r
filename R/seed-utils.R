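#' Derive a named sub-seed from a master seed
#'
#' All randomness in the package flows from one master seed through named
#' substreams, so that individual stages (splitting, extraction, classifier
#' training, simulation) can be re-run independently yet reproducibly.
#'
#' @param master integer master seed.
#' @param stream character name of the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  h <- as.double(master %% 2147483647)
  for (k in utf8ToInt(stream)) {
    # 31-bit multiplicative hash; doubles keep exact integer arithmetic < 2^53
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
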
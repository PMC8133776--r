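#' Derive a reproducible substream seed
#'
#' All stochastic operations in the package draw from independent substreams
#' derived from one root seed. The substream seed is a stable (platform- and
#' session-independent) hash of the root seed and the operation name, so that
#' adding a new stochastic step to a pipeline never perturbs the draws of the
#' existing ones.
#'
#' @param seed Integer root seed.
#' @param op Character scalar naming the operation (e.g. `"simulate_genome"`).
#' @return An integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' substream_seed(1L, "simulate_genome")
#' @export
substream_seed <- function(seed, op) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(op),
            length(op) == 1L)
  # 32-bit FNV-1a over the operation name, folded with the seed.
  h <- 2166136261
  for (b in utf8ToInt(op)) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b))
    h <- (abs(h) * 16777619) %% 2147483629
  }
  as.integer((abs(h) + abs(as.numeric(seed)) * 2654435761) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_substream <- function(seed, op, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, op))
  expr
}
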
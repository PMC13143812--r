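# Seed discipline: every generator is a pure function of (config, seed).
# with_seed() runs code under a temporary RNG state and restores the caller's
# stream afterwards, so package functions never perturb user RNG state.
# derive_seed() gives named substreams (per stage, per agent) from one root
# seed, so batch order never affects per-agent results.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible substream seed
#'
#' Combines a root seed with a character key (stage name, agent id) into a
#' deterministic 31-bit seed, so per-agent simulation streams are independent
#' of batch order.
#'
#' @param seed integer root seed.
#' @param key character key naming the substream.
#' @return A single integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, key) {
  m <- 2147483647  # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(paste(key, collapse = "|"))) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}
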
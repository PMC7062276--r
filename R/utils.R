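## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. All stochastic entry points funnel through this, so a given
## (seed, arguments) pair always reproduces the same output.
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }, add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Deterministic per-stage child seeds
#'
#' Expands one master seed into per-stage seeds (master folded into
#' `[0, 2^31 / 1000)` then offset by the stage index), so every stage of a
#' multi-stage pipeline is independently reproducible from the master seed
#' recorded in a run manifest.
#'
#' @param seed Master integer seed.
#' @param stage Integer stage index.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  (as.integer(seed) %% 2147483L) * 1000L + as.integer(stage)
}

.assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name))
  }
  invisible(x)
}
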
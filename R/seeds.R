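#' Derive a deterministic child seed
#'
#' One master seed governs a whole run; every stochastic sub-task (one size
#' distribution, one replicate, one sweep combination) draws its own child
#' seed deterministically from the master seed and a sequence of small
#' non-negative indices. The mixing is a fixed-odds integer hash kept inside
#' the 32-bit signed range so the result is always a valid R seed.
#'
#' @param master Integer master seed.
#' @param ... Integer indices (distribution index, replicate number, ...).
#' @return A single integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' child_seed(1, 3)      # distribution 3 of run 1
#' child_seed(1, 3, 12)  # replicate 12 thereof
child_seed <- function(master, ...) {
  idx <- c(...)
  stopifnot(length(master) == 1L, is.finite(master))
  h <- as.double(master) %% 2147483647
  for (k in c(idx, length(idx))) {
    stopifnot(is.finite(k))
    # 48271 is a classic Lehmer multiplier; arithmetic stays exact in doubles
    h <- (h * 48271 + as.double(k) %% 2147483647 + 1) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
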
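#' Derive a reproducible sub-seed
#'
#' Maps a master seed and an index to a new seed, so that batched simulations
#' (one sub-seed per agent) can be reproduced in isolation. The map is a fixed
#' affine hash modulo `2^31 - 1`, keeping every derived seed a valid R integer.
#'
#' @param seed Master integer seed.
#' @param i Positive integer index (e.g. agent number).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, 1)
derive_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(i))
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647)
}

# condition labels, in canonical order, shared across modules
condition_levels <- function() c("self", "other", "no_one")

assert_conditions <- function(x) {
  bad <- setdiff(unique(as.character(x)), condition_levels())
  if (length(bad) > 0L) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
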
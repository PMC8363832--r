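# Internal helpers shared across modules.

#' Derive a per-replicant child seed from a master seed
#'
#' Deterministic 32-bit mixing of the master seed and the replicant index so
#' that replicants are individually reproducible and mutually independent
#' regardless of execution order.
#'
#' @param master_seed Integer master seed for the whole ensemble.
#' @param replicant Integer replicant index (1-based).
#' @return A single integer seed in `[1, 2^31 - 1]`.
#' @export
#' @examples
#' child_seed(42, 1)
#' child_seed(42, 2)
child_seed <- function(master_seed, replicant) {
  stopifnot(length(master_seed) == 1L, length(replicant) == 1L,
            is.finite(master_seed), is.finite(replicant))
  m <- as.double(abs(as.integer(master_seed))) %% 2147483647
  r <- as.double(abs(as.integer(replicant)))
  # Lehmer-style multiplicative mix; all intermediates stay below 2^53.
  x <- (m * 48271 + r * 104729 + 1) %% 2147483629
  x <- (x * 16807) %% 2147483647
  as.integer(x) + 1L
}

# Set the RNG state only when a seed is supplied.
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}
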
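#' Derive a reproducible child seed from a master seed
#'
#' Deterministically maps a master seed plus any number of integer stream
#' identifiers (subject index, condition, replicate, ...) to a positive
#' 32-bit seed, using a Lehmer-style multiplicative congruential hash.
#' Independent identifier tuples give (for practical purposes) independent
#' RNG streams, so datasets, conditions and replicates can be generated
#' reproducibly and independently from a single master seed.
#'
#' @param master Integer master seed.
#' @param ... Integer stream identifiers.
#' @return A single integer in `[1, 2^31 - 20]`.
#' @export
#' @examples
#' derive_seed(1, 3, 2)
derive_seed <- function(master, ...) {
  comps <- c(...)
  h <- as.double(master) %% 2147483647
  for (k in comps) {
    # 48271 * 2^31 < 2^53: exact in double arithmetic
    h <- (h * 48271 + as.double(k) + 1) %% 2147483647
  }
  h <- (h * 48271 + 1) %% 2147483647
  as.integer(h %% 2147483629 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
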
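#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic stage of the package draws its own seed from the master
#' seed through this splitting rule, so that a single integer fixes all
#' randomness end to end while stages stay independent of each other's
#' draw counts.
#'
#' @param seed master seed (integer).
#' @param offset stage index (non-negative integer).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(offset), length(offset) == 1L, offset >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(seed) %% m)
  # multiplicative hop (Park-Miller multiplier) keeps consecutive offsets
  # far apart in seed space
  for (i in seq_len(offset + 1L)) s <- (s * 48271 + 11) %% m
  as.integer(s)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# stop() with a class so callers can condition-handle specific failures
pf_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "phylofauna_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
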
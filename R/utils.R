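#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' All randomness in the package flows from a single integer master seed.
#' Stage- and gene-specific seeds are derived deterministically from the
#' master seed and a string key (stage name, gene id), so that serial and
#' parallel runs agree and adding draws to one stage does not shift another
#' stage's stream.
#'
#' @param master integer master seed.
#' @param key character scalar naming the consumer (e.g. "module_search" or a
#'   gene id).
#' @return an integer in \code{[0, 2^31 - 2]} suitable for \code{set.seed()}.
#' @export
derive_seed <- function(master, key) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(key),
            length(key) == 1L)
  m <- 2147483629 # prime below 2^31, keeps seeds in 32-bit integer range
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% m
  as.integer((abs(master) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under `seed` without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Empirical p-value with the (+1)/(+1) correction: never returns 0, and the
# attainable floor is 1/(n+1).
empirical_pvalue <- function(n_as_extreme, n_draws) {
  (n_as_extreme + 1) / (n_draws + 1)
}
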
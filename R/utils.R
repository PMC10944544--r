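# Shared internal helpers.

#' Derive independent substream seeds from one master seed
#'
#' One user-facing seed is expanded into reproducible per-component
#' seeds so that, e.g., adding plots to a study does not perturb the
#' draws of earlier plots. Seeds are drawn once from a generator seeded
#' with the master seed and kept below 2^31.
#'
#' @param seed master integer seed
#' @param n number of substream seeds
#' @return integer vector of length `n`
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed), n >= 0)
  if (n == 0) return(integer(0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

# run expr with a local RNG stream (restores caller's stream afterwards)
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
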
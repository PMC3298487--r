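#' Derive a named substream seed from a root seed
#'
#' Every stochastic stage of the package draws its own seed from the user's
#' root seed plus a stage name, so that adding or reordering stages never
#' perturbs the random numbers of the others. The mapping is a fixed integer
#' hash; the result is always a valid 32-bit seed.
#'
#' @param seed integer root seed.
#' @param name character stage name, e.g. `"expression"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}
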
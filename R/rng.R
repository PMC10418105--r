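#' Derive a child seed from a top-level seed and a stage name
#'
#' All randomness in the package flows from one explicit integer seed.
#' Stage-specific child seeds are derived by stable string hashing of the
#' stage name, so that adding a stage never perturbs the random stream of
#' another stage.
#'
#' @param seed Top-level integer seed.
#' @param name Stage name (character scalar).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name), length(name) == 1L)
  h <- 0
  m <- 2147483647  # 2^31 - 1, keeps every derived seed a valid 32-bit R integer
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% m
  as.integer((h + as.numeric(seed) %% m * 31) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards, so no global RNG state leaks.
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
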
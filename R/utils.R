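#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to a fixed state, evaluates, and restores the caller's RNG
#' state, so seeded simulation never perturbs the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @export
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child-seed derivation, kept inside 32-bit integer range.
.childSeed <- function(seed, i, salt = 0L) {
  as.integer((as.double(seed) * 1009 + as.double(i) * 9973 +
                as.double(salt) * 31627) %% 2147483647)
}
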
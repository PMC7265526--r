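# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
# expr is a promise evaluated in the calling frame, so assignments inside
# the braces land in the caller's environment.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  invisible(force(expr))
}

#' Derive a stream seed from a master seed and a string label
#'
#' Deterministic 31-bit seed derived by a polynomial rolling hash of the
#' label folded into the master seed, so each (seed, dataset) pair gets its
#' own reproducible RNG stream.
#'
#' @param master integer master seed.
#' @param label character(1) stream label (e.g. a dataset id).
#' @return integer in [0, 2^31 - 2].
#' @export
deriveSeed <- function(master, label) {
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(as.character(label)))
    h <- (h * 131 + code) %% m
  as.integer(h)
}

.gm <- function(x) exp(mean(log(x)))
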
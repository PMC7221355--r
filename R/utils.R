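#' @useDynLib betticonn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor pchisq pnorm qchisq qnorm rnorm runif sd var
#'   binomial coef glm glm.fit predict quantile residuals
#' @importFrom graphics abline axis segments
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based derivation (a Lehmer step plus a counter offset, reduced
#' modulo the Mersenne prime 2^31 - 1) so that per-subject or per-permutation
#' streams are independent of evaluation order and safe to parallelize.
#'
#' @param seed Master seed (integer).
#' @param counter Non-negative integer counter (subject or permutation index).
#' @return An integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  m <- 2147483647
  s <- (abs(as.double(seed)) %% m) + 1
  s <- (s * 48271) %% m
  s <- (s + as.double(counter) * 2246822519) %% m
  as.integer(if (s == 0) 1 else s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
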
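#' @useDynLib oscmvpa, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef ks.test lm pnorm qnorm qt quantile rnorm
#'   runif sd var
NULL

#' Evaluate an expression under a fixed RNG state
#'
#' Sets the seed, evaluates `expr`, and restores the caller's random stream,
#' so seeded sub-computations never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
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

#' Derive a reproducible sub-stream seed
#'
#' Mixes a base seed with one or more stream indices through a Lehmer-style
#' congruential step so that independent analyses (subjects, permutations,
#' folds) get decorrelated but fully reproducible seeds. Result is always in
#' `[1, 2^31 - 2]`.
#'
#' @param seed base integer seed.
#' @param ... integer stream indices (e.g. subject number, permutation number).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- as.numeric(seed) %% m
  for (k in c(...)) {
    x <- (x * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(x %% (m - 1) + 1)
}

# Percentile with linear interpolation between order statistics
# (stats::quantile type 7), the convention fixed for all rejection and
# null-distribution thresholds.
percentile <- function(x, p) {
  unname(stats::quantile(x, p, type = 7, names = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
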
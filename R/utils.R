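#' @useDynLib psgres, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft median quantile rnorm runif rpois sd pt t.test setNames
#' @importFrom utils head tail write.csv read.csv
NULL

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a child seed from a parent seed and a stream
# index, staying inside the 32-bit signed range R requires.
derive_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1103 * as.double(index)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob_matrix <- function(m, name = deparse(substitute(m)), tol = 1e-9) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(sprintf("`%s` must be a square matrix", name), call. = FALSE)
  if (any(m < -tol))
    stop(sprintf("`%s` has negative entries", name), call. = FALSE)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol))
    stop(sprintf("rows of `%s` must sum to 1 (max deviation %.3g)",
                 name, max(abs(rs - 1))), call. = FALSE)
  invisible(TRUE)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
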
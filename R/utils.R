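#' @useDynLib runeven, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef lm median quantile rnorm runif sd approx var
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so generators are pure functions
#' of their `seed` argument without clobbering the global stream.
#'
#' @param seed integer seed
#' @param code expression to evaluate
#' @return value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive per-stage seeds from one global seed
#'
#' @param seed global integer seed
#' @param n number of child seeds
#' @return integer vector of `n` seeds, all below 2^31
#' @export
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# centered moving average with edge shrinkage; k forced odd
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k == 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  h <- (k - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# numerical gradient on a uniform grid (central differences, one-sided ends)
grad_uniform <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  g <- numeric(n)
  g[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  g[1L] <- (x[2L] - x[1L]) / dt
  g[n] <- (x[n] - x[n - 1L]) / dt
  g
}

# contiguous runs of TRUE; returns matrix with columns start, end
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
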
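#' @useDynLib periglia, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile rnorm runif rpois rbinom mad fft sd
#'   aggregate lm coef uniroot approx qt qnorm
#' @importFrom utils head tail read.csv write.csv
NULL

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Every stochastic entry point in the
# package goes through this so that no call mutates global RNG state.
with_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# uniform point on the unit sphere / quasi-uniform Fibonacci lattice
# (memoized: the lattice is deterministic and reused heavily)
.fib_cache <- new.env(parent = emptyenv())
fibonacci_sphere <- function(n) {
  key <- as.character(n)
  if (!is.null(.fib_cache[[key]])) return(.fib_cache[[key]])
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  out <- cbind(z = cos(phi), y = sin(phi) * sin(theta),
               x = sin(phi) * cos(theta))
  .fib_cache[[key]] <- out
  out
}

random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# rotation matrix sending e1 (z-axis in our (z,y,x) frame) nowhere special:
# a uniformly random 3x3 rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
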
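#' @keywords internal
"_PACKAGE"

#' @importFrom stats aov TukeyHSD oneway.test wilcox.test t.test p.adjust
#'   pf pt rnorm runif rpois cor cov fft mvfft sd var complete.cases setNames
#' @importFrom utils write.csv read.csv head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
with_seed <- function(seed, expr) {
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

rms <- function(x) sqrt(mean(x^2))

# Smallest 5-smooth (2^a 3^b 5^c) integer >= n: mixed-radix FFTs degrade to
# quadratic cost on lengths with large prime factors, so transforms are
# padded to the next fast length.
next_fast_len <- function(n) {
  if (n <= 6) return(n)
  best <- Inf
  p5 <- 1
  while (p5 < best) {
    p35 <- p5
    while (p35 < best) {
      p <- p35 * 2^max(0, ceiling(log2(n / p35)))
      if (p >= n && p < best) best <- p
      if (p35 >= n && p35 < best) best <- p35
      p35 <- p35 * 3
    }
    p5 <- p5 * 5
  }
  as.integer(best)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
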
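#' @importFrom stats dgamma median optim rnorm runif sd var setNames fft mvfft quantile
#' @importFrom utils head tail
NULL

# Deterministic child seeds: Lehmer-style mixing, always < 2^31 - 1.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.double(seed) %% 2147483646) + 1
  for (k in idx) {
    s <- (s * 48271 + as.double(k) + 11) %% 2147483647
  }
  as.integer(s %% 2147483645) + 1L
}

with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

# log(1 + exp(z)) without overflow
softplus <- function(z) {
  out <- numeric(length(z))
  hi <- z > 30
  out[hi] <- z[hi]
  out[!hi] <- log1p(exp(z[!hi]))
  out
}

# logistic with guard
sigmoid <- function(z) 1 / (1 + exp(pmin(pmax(-z, -700), 700)))

row_norms <- function(x) sqrt(rowSums(x^2))
col_norms <- function(x) sqrt(colSums(x^2))

vec_norm <- function(x) sqrt(sum(x^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}
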
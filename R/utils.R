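#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif rpois density median sd mad cor ecdf
#'   filter nextn optimize uniroot quantile approx
#' @importFrom utils read.csv write.csv head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive a child seed (< 2^31) from a parent seed and a
# stage label, so that one pipeline seed reproduces every stage.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  bytes <- utf8ToInt(as.character(stage))
  h <- sum(bytes * seq_along(bytes) * 131)
  as.integer((abs(seed) * 48271 + h) %% 2147483587 + 1)
}

vnorm <- function(v) sqrt(sum(v^2))

# Moving-average smoothing with edge padding, window length n samples.
smooth_ma <- function(x, n) {
  if (n <= 1L) return(x)
  n <- as.integer(n)
  xp <- c(rep(x[1], n), x, rep(x[length(x)], n))
  y <- stats::filter(xp, rep(1 / n, n), sides = 2)
  as.numeric(y[(n + 1):(n + length(x))])
}

# FFT-based analytic signal; Mod() of the result is the envelope.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Gaussian pink (1/f^exponent power) noise, unit variance, spectral
# synthesis with a low-frequency shelf at f_min to keep power finite.
pink_noise <- function(n, fs, exponent = 1, f_min = 0.5) {
  stopifnot(n > 1)
  m <- stats::nextn(n, 2)
  f <- c(0, seq_len(m - 1)) * fs / m
  f[f > fs / 2] <- fs - f[f > fs / 2]  # mirror for negative frequencies
  shape <- numeric(m)
  pos <- f > 0
  shape[pos] <- pmin(f[pos], Inf)
  shape[pos] <- (pmax(f[pos], f_min))^(-exponent / 2)
  shape[1] <- 0
  z <- stats::fft(stats::rnorm(m)) * shape
  x <- Re(stats::fft(z, inverse = TRUE) / m)[seq_len(n)]
  x / stats::sd(x)
}
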
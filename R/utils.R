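#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif sd cor qt pt median mad quantile rbinom
#'   rpois qlogis plogis cor.test var complete.cases setNames ks.test
#' @importFrom utils head write.csv read.csv write.table read.table
NULL

# Derive a reproducible 32-bit substream seed from a master seed and a
# stage label, so pipeline stages can be re-run in isolation.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Hann taper of length n (periodic = FALSE gives the symmetric window
# conventionally used for spectral analysis of finite epochs).
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Analytic signal via FFT (Hilbert transform); x a numeric vector.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Spectrally shaped Gaussian noise: n samples x m series, unit variance,
# amplitude response g(f) over the two-sided frequency magnitude grid.
shaped_noise <- function(n, m, gain_fun, fs) {
  stopifnot(n > 4)
  f <- seq(0, fs, length.out = n + 1)[1:n]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- gain_fun(f)
  # draw the spectrum directly (iid complex Gaussian x gain); the real part
  # of its inverse transform is stationary Gaussian with PSD g^2. Only
  # non-null bins are drawn (narrowband gains are mostly zero).
  nz <- which(g > 0)
  Z <- matrix(complex(real = 0), n, m)
  Z[nz, ] <- matrix(complex(real = rnorm(length(nz) * m),
                            imaginary = rnorm(length(nz) * m)),
                    length(nz)) * g[nz]
  x <- Re(stats::mvfft(Z, inverse = TRUE)) / sqrt(n)
  sdv <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sweep(x, 2, pmax(sdv, 1e-300), `/`)
}

# 1/f^alpha noise: n samples at rate fs, unit variance (m series).
one_over_f_noise <- function(n, alpha, fs, m = 1) {
  out <- shaped_noise(n, m, function(f) c(0, f[-1]^(-alpha / 2)), fs)
  if (m == 1) out[, 1] else out
}

# Band-limited Gaussian noise via hard FFT masking: flat power inside
# [lo, hi] Hz, zero outside. Unit variance (m series).
narrowband_noise <- function(n, lo, hi, fs, m = 1) {
  out <- shaped_noise(n, m, function(f) as.numeric(f >= lo & f <= hi), fs)
  if (m == 1) out[, 1] else out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
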
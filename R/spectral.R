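# Sensor-level spectral power and the offline reimplementation of the
# autoregressive (maximum-entropy) cursor control signal.

#' Hann-taper power spectrum, 1-50 Hz in 1-Hz steps
#'
#' Per-trial single-window Hann-tapered periodogram. With 1-second windows
#' the native resolution is 1 Hz, so bins coincide with integer frequencies.
#' Normalization: `P(f) = 2 |sum_t w_t x_t e^(-i 2 pi f t)|^2 / sum_t w_t^2`,
#' i.e. taper-power-corrected one-sided power per bin (microvolts squared);
#' this makes a unit-amplitude in-bin sinusoid integrate to its variance
#' across the peak bins.
#'
#' @param data an `epoched_eeg`; window length must give at least 1 Hz
#'   resolution (>= 1 s).
#' @param fmin,fmax frequency range (defaults 1 and 50 Hz).
#' @param average average over trials (default `FALSE`: per-trial spectra).
#' @return object of class `spectral_data`: `power`
#'   (trials x channels x freqs, or channels x freqs when averaged),
#'   `freqs`, `meta` (the trial metadata).
#' @export
compute_power_spectrum <- function(data, fmin = 1, fmax = 50, average = FALSE) {
  fs <- data$sampling_rate
  d <- dim(data$data)
  ns <- d[3]
  if (ns / fs < 1) stop("window too short for 1 Hz resolution")
  freqs <- seq(fmin, fmax, by = 1)
  bins <- round(freqs * ns / fs) + 1            # FFT bin indices (1-based)
  if (max(freqs) > fs / 2) stop("fmax above Nyquist")
  w <- hann_window(ns)
  u <- sum(w^2)
  m <- matrix(aperm(data$data, c(3, 1, 2)), nrow = ns)   # samples x (trials*channels)
  X <- stats::mvfft(m * w)
  P <- 2 * (Mod(X[bins, , drop = FALSE])^2) / u
  pow <- aperm(array(P, dim = c(length(freqs), d[1], d[2])), c(2, 3, 1))
  if (average) pow <- apply(pow, c(2, 3), mean)
  dimnames(pow)[[length(dim(pow)) - 1]] <- data$montage$channel_names
  structure(list(power = pow, freqs = freqs, meta = data$trial_meta,
                 channel_names = data$montage$channel_names),
            class = "spectral_data")
}

#' Burg (maximum entropy) AR spectrum
#'
#' Fits an AR(p) model by the Burg recursion (which minimizes summed
#' forward and backward prediction error under the Levinson constraint) and
#' evaluates the parametric spectrum
#' `S(f) = sigma^2 / |1 - sum_k a_k e^(-i 2 pi f k / fs)|^2`.
#'
#' @param signal numeric samples.
#' @param order AR order; must be below `length(signal)/2`.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate in Hz.
#' @param amplitude return the amplitude spectrum `sqrt(S)` (default) or
#'   power.
#' @return list with `spectrum` (at `freqs`), `ar` (coefficients a_k such
#'   that `x_t = sum a_k x_{t-k} + e_t`), `sigma2`.
#' @export
burg_ar_spectrum <- function(signal, order, freqs, fs, amplitude = TRUE) {
  fit <- burg_fit(signal, order)
  S <- ar_spectrum(fit$ar, fit$sigma2, freqs, fs)
  list(spectrum = if (amplitude) sqrt(S) else S, ar = fit$ar,
       sigma2 = fit$sigma2)
}

# Burg recursion; returns a_k (predictor convention) and innovation variance.
burg_fit <- function(x, order) {
  n <- length(x)
  if (order >= n / 2) stop("order must be below half the sample count")
  f <- x; b <- x
  a <- numeric(0)
  E <- mean(x^2)
  for (k in seq_len(order)) {
    ff <- f[(k + 1):n]
    bb <- b[k:(n - 1)]
    den <- sum(ff^2) + sum(bb^2)
    if (den < .Machine$double.eps * n)
      stop("numerically singular reflection coefficient at order ", k)
    kk <- -2 * sum(ff * bb) / den
    a <- c(a, 0) + kk * c(rev(a), 1)
    E <- E * (1 - kk^2)
    fn <- ff + kk * bb
    bn <- bb + kk * ff
    f <- c(rep(0, k), fn)
    b <- c(rep(0, k), bn)
  }
  list(ar = -a, sigma2 = E)
}

ar_spectrum <- function(ar, sigma2, freqs, fs) {
  k <- seq_along(ar)
  H <- vapply(freqs, function(f)
    abs(1 - sum(ar * exp(-2i * pi * f * k / fs)))^2, numeric(1))
  sigma2 / H
}

#' Small-Laplacian spatial filter
#'
#' Center channel minus the mean of its four nearest in-plane neighbours.
#'
#' @param data an `epoched_eeg`.
#' @param center channel name (e.g. `"C3"`).
#' @return trials x samples matrix of Laplacian-filtered signal.
#' @export
small_laplacian <- function(data, center) {
  ch <- data$montage$channel_names
  nb <- montage_neighbors(data$montage, center, 4)
  if (!all(nb %in% ch)) stop("missing neighbor channels for ", center)
  ci <- match(center, ch); ni <- match(nb, ch)
  d <- dim(data$data)
  ctr <- matrix(data$data[, ci, ], d[1], d[3])
  ctr - apply(data$data[, ni, , drop = FALSE], c(1, 3), mean)
}

#' Offline sensorimotor-rhythm control signal
#'
#' Reimplements the online cursor control chain: every 40 ms, a Burg AR
#' spectrum (default order 16) of the trailing 160 ms of the small-Laplacian
#' filtered C3 and C4 signals is evaluated on a 0.5-Hz grid, the amplitude
#' is averaged over the 3-Hz bin surrounding 12 Hz (10.5-13.5 Hz), each
#' electrode's amplitude is z-normalized by an exponentially weighted
#' running mean/variance (30 s time constant), and the control value is the
#' normalized difference (horizontal) and negative normalized sum
#' (vertical; high bilateral SMR amplitude during rest drives the cursor
#' down).
#'
#' @param data an `epoched_eeg` containing C3, C4 and their neighbours.
#' @param order AR order.
#' @param window_sec trailing AR window (s).
#' @param update_sec update interval (s).
#' @param band amplitude-averaging band (Hz).
#' @param tau_sec normalization time constant (s).
#' @param norm_state optional running-normalization state from a previous
#'   call (e.g. trained on a baseline run), to continue across runs.
#' @param adapt keep adapting the normalization state (default `TRUE`);
#'   with `FALSE` a supplied `norm_state` is applied frozen, the online
#'   convention when a session baseline has already calibrated it.
#' @return object of class `control_signal_trace`: data.frame `values`
#'   (trial, time, c3, c4, horizontal, vertical), `update_interval`, and the
#'   final `norm_state`.
#' @export
control_signal <- function(data, order = 16, window_sec = 0.16,
                           update_sec = 0.04, band = c(10.5, 13.5),
                           tau_sec = 30, norm_state = NULL, adapt = TRUE) {
  fs <- data$sampling_rate
  W <- round(window_sec * fs)
  U <- round(update_sec * fs)
  if (W <= 2 * order) stop("insufficient samples in AR window for order ", order)
  lc3 <- small_laplacian(data, "C3")
  lc4 <- small_laplacian(data, "C4")
  fgrid <- seq(band[1], band[2], by = 0.5)
  alpha <- update_sec / tau_sec
  st <- norm_state %||% list(
    c3 = list(m = 0, v = 0, n = 0), c4 = list(m = 0, v = 0, n = 0))
  # exponentially weighted mean/variance; early updates use a growing
  # window (effective alpha 1/(n+1)) so the state is unbiased from the start
  upd <- function(s, x) {
    if (!adapt) { s$n <- s$n + 1; return(s) }
    a <- max(1 / (s$n + 1), alpha)
    s$m <- (1 - a) * s$m + a * x
    s$v <- (1 - a) * s$v + a * (x - s$m)^2
    s$n <- s$n + 1
    s
  }
  rows <- list()
  ns <- ncol(lc3)
  for (tr in seq_len(nrow(lc3))) {
    starts <- seq(W, ns, by = U)
    for (t0 in starts) {
      seg3 <- lc3[tr, (t0 - W + 1):t0]
      seg4 <- lc4[tr, (t0 - W + 1):t0]
      a3 <- mean(burg_ar_spectrum(seg3, order, fgrid, fs)$spectrum)
      a4 <- mean(burg_ar_spectrum(seg4, order, fgrid, fs)$spectrum)
      st$c3 <- upd(st$c3, a3)
      st$c4 <- upd(st$c4, a4)
      z3 <- (a3 - st$c3$m) / sqrt(st$c3$v + 1e-12)
      z4 <- (a4 - st$c4$m) / sqrt(st$c4$v + 1e-12)
      rows[[length(rows) + 1]] <- data.frame(
        trial = tr, time = t0 / fs, c3 = z3, c4 = z4,
        horizontal = z3 - z4, vertical = -(z3 + z4))
    }
  }
  structure(list(values = do.call(rbind, rows), update_interval = update_sec,
                 norm_state = st),
            class = "control_signal_trace")
}
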
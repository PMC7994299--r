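# Offline preprocessing chain:
# filter -> resample -> interpolate -> reference -> ICA -> window -> rejection.
#
# Filters are zero-phase frequency-domain filters with raised-cosine
# transition bands applied to mirror-padded epochs. A windowed-FIR design
# with the nominal 25% transition width would need ~13k taps at a 1 Hz edge
# and 1 kHz sampling — longer than any epoch — so the frequency-sampling
# design is used instead; it is exactly zero-phase, has no passband ripple,
# and is fully attenuating beyond the stop edge.

# Zero-phase band filter on a samples x series matrix.
# Passband [f1p, f2p]; raised-cosine transitions down to f1s and up to f2s.
fft_band_filter <- function(x, fs, f1s, f1p, f2p, f2s) {
  n <- nrow(x)
  pad <- min(n - 1, max(16, round(n / 2)))
  xp <- rbind(x[rev(seq_len(pad) + 1), , drop = FALSE],
              x,
              x[n - seq_len(pad), , drop = FALSE])
  np <- nrow(xp)
  f <- seq(0, fs, length.out = np + 1)[1:np]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  H <- numeric(np)
  H[f >= f1p & f <= f2p] <- 1
  lo <- f > f1s & f < f1p
  H[lo] <- 0.5 - 0.5 * cos(pi * (f[lo] - f1s) / (f1p - f1s))
  hi <- f > f2p & f < f2s
  H[hi] <- 0.5 + 0.5 * cos(pi * (f[hi] - f2p) / (f2s - f2p))
  y <- Re(stats::mvfft(stats::mvfft(xp) * H, inverse = TRUE)) / np
  y[pad + seq_len(n), , drop = FALSE]
}

# Apply a samples-domain matrix operation channel/trial-wise to an array.
apply_samplewise <- function(arr, fun) {
  d <- dim(arr)
  m <- matrix(aperm(arr, c(3, 1, 2)), nrow = d[3])   # samples x (trials*channels)
  out <- fun(m)
  aperm(array(out, dim = c(nrow(out), d[1], d[2])), c(2, 3, 1))
}

#' Zero-phase band-pass filter
#'
#' @param data an `epoched_eeg`.
#' @param low,high passband edges in Hz; `0 < low < high < fs/2`.
#'   Attenuation reaches at least 20 dB by `low/2` and by
#'   `min(2*high, 0.99*Nyquist)`; the passband is ripple-free.
#' @return filtered `epoched_eeg`.
#' @export
bandpass_filter <- function(data, low, high) {
  fs <- data$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("invalid band [", low, ", ", high, "] for sampling rate ", fs)
  f2s <- min(2 * high, 0.99 * fs / 2)
  out <- apply_samplewise(data$data, function(m)
    fft_band_filter(m, fs, low / 2, low, high, f2s))
  set_data(data, out)
}

#' Anti-aliased integer-factor resampling
#'
#' @param data an `epoched_eeg`.
#' @param target_rate new rate in Hz; must divide the current rate.
#' @return resampled `epoched_eeg`.
#' @export
resample <- function(data, target_rate) {
  fs <- data$sampling_rate
  if (target_rate >= fs) stop("upsampling not supported (", target_rate,
                              " >= ", fs, ")")
  k <- fs / target_rate
  if (abs(k - round(k)) > 1e-9)
    stop("target_rate must divide the sampling rate")
  k <- round(k)
  nyq_new <- target_rate / 2
  low <- apply_samplewise(data$data, function(m)
    fft_band_filter(m, fs, 0, 0, 0.8 * nyq_new, nyq_new))
  out <- low[, , seq(1, dim(low)[3], by = k), drop = FALSE]
  set_data(data, out, sampling_rate = target_rate)
}

# Perrin spherical-spline basis g(x) = 1/(4pi) sum (2n+1)/(n(n+1))^m P_n(x).
spline_g <- function(x, m = 4, nterms = 50) {
  x <- pmin(1, pmax(-1, x))
  Pnm1 <- rep(1, length(x)); Pn <- x
  out <- 3 / 2^m * Pn
  for (n in 2:nterms) {
    Pnp1 <- ((2 * n - 1) * x * Pn - (n - 1) * Pnm1) / n
    Pnm1 <- Pn; Pn <- Pnp1
    out <- out + (2 * n + 1) / (n * (n + 1))^m * Pn
  }
  out / (4 * pi)
}

#' Spherical-spline interpolation of bad channels
#'
#' Perrin-style spline (order m = 4, 50 Legendre terms, ridge 1e-5) fitted
#' on the good channels and evaluated at the bad channel positions; good
#' channels pass through unchanged.
#'
#' @param data an `epoched_eeg`.
#' @param bad character vector of bad channel names (fewer than a quarter
#'   of the montage).
#' @return `epoched_eeg` with bad channels replaced.
#' @export
interpolate_bad_channels <- function(data, bad) {
  if (length(bad) == 0) return(data)
  ch <- data$montage$channel_names
  if (!all(bad %in% ch)) stop("bad channels not in montage")
  if (length(bad) >= length(ch) / 4) stop("too many bad channels")
  bi <- match(bad, ch); gi <- setdiff(seq_along(ch), bi)
  P <- data$montage$positions3d
  cosang <- P %*% t(P)
  G <- spline_g(cosang[gi, gi])
  ng <- length(gi)
  A <- rbind(cbind(G + diag(1e-5, ng), 1), c(rep(1, ng), 0))
  Gb <- spline_g(cosang[bi, gi, drop = FALSE])
  d <- dim(data$data)
  for (tr in seq_len(d[1])) {
    Y <- rbind(matrix(data$data[tr, gi, ], nrow = ng), 0)
    W <- solve(A, Y)
    est <- Gb %*% W[seq_len(ng), , drop = FALSE] +
      matrix(W[ng + 1, ], length(bi), d[3], byrow = TRUE)
    data$data[tr, bi, ] <- est
  }
  data
}

#' Common-average reference
#'
#' Subtracts the instantaneous mean across channels, making every sample's
#' channel mean zero. Idempotent.
#'
#' @param data an `epoched_eeg`.
#' @return re-referenced `epoched_eeg`.
#' @export
common_average_reference <- function(data) {
  d <- dim(data$data)
  means <- apply(data$data, c(1, 3), mean)                    # trials x samples
  data$data <- data$data - aperm(array(means, c(d[1], d[3], d[2])), c(1, 3, 2))
  data
}

#' Build ocular ICA artifact templates
#'
#' Synthetic stand-ins for template topographies averaged over manually
#' labeled artifact components: a frontal monopolar eyeblink map (Gaussian
#' fall-off from the Fpz direction) and a bipolar horizontal-EOG map
#' (left-right frontal gradient). Unit-norm, average-referenced.
#'
#' @param montage a `sensor_montage`.
#' @return object of class `ica_templates`: `template_topographies`
#'   (2 x channels, rows `blink`, `eog`).
#' @export
make_ica_templates <- function(montage) {
  P <- montage$positions3d
  fpz <- planar_to_sphere(matrix(c(0, 1), 1))
  blink <- exp(-2.5 * colSums((t(P) - as.numeric(fpz))^2))
  f7 <- planar_to_sphere(matrix(c(-0.9, 0.45), 1))
  f8 <- planar_to_sphere(matrix(c(0.9, 0.45), 1))
  eog <- exp(-3 * colSums((t(P) - as.numeric(f7))^2)) -
    exp(-3 * colSums((t(P) - as.numeric(f8))^2))
  tt <- rbind(blink = blink - mean(blink), eog = eog - mean(eog))
  tt <- tt / sqrt(rowSums(tt^2))
  colnames(tt) <- montage$channel_names
  structure(list(template_topographies = tt), class = "ica_templates")
}

# Symmetric FastICA (tanh contrast) on pre-whitened data Z (k x T).
# Returns the unmixing matrix W (k x k, rows orthonormal).
fastica_core <- function(Z, tol = 1e-7, maxit = 500) {
  k <- nrow(Z); Tn <- ncol(Z)
  W <- matrix(rnorm(k * k), k)
  W <- sym_decorrelate(W)
  for (it in seq_len(maxit)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Wnew <- G %*% t(Z) / Tn - diag(rowMeans(1 - G^2)) %*% W
    Wnew <- sym_decorrelate(Wnew)
    delta <- max(abs(abs(rowSums(Wnew * W)) - 1))
    W <- Wnew
    if (delta < tol) return(list(W = W, converged = TRUE, iter = it))
  }
  list(W = W, converged = FALSE, iter = maxit)
}

sym_decorrelate <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

#' Remove ocular components by ICA template matching
#'
#' PCA reduces the concatenated epochs to `n_pca` dimensions, a seeded
#' symmetric FastICA estimates `n_pca` components, and for each of the two
#' artifact templates the component whose channel-space mixing map has the
#' largest absolute Pearson correlation with the template is zeroed
#' (exactly two components removed). Non-convergent ICA is retried with a
#' fresh seed.
#'
#' @param data an `epoched_eeg`.
#' @param templates an `ica_templates`.
#' @param n_pca PCA dimensionality (default 30).
#' @param n_ic number of independent components; must equal `n_pca`.
#' @param seed RNG seed for ICA initialization.
#' @param max_retries retries on non-convergence.
#' @return `epoched_eeg` with an attribute `ica_report` (removed component
#'   indices, template correlations, convergence info).
#' @export
remove_ocular_components <- function(data, templates, n_pca = 30, n_ic = n_pca,
                                     seed = 1, max_retries = 3) {
  d <- dim(data$data)
  if (n_pca > d[2]) stop("n_pca exceeds channel count")
  if (n_ic != n_pca) stop("n_ic must equal n_pca")
  X <- matrix(aperm(data$data, c(2, 3, 1)), nrow = d[2])  # channels x (samples*trials)
  mu <- rowMeans(X)
  Xc <- X - mu
  e <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)
  E <- e$vectors[, seq_len(n_pca), drop = FALSE]
  lam <- pmax(e$values[seq_len(n_pca)], 1e-12)
  Z <- diag(1 / sqrt(lam)) %*% t(E) %*% Xc              # whitened, n_pca x T
  fit <- NULL
  for (r in 0:max_retries) {
    fit <- with_seed(seed + r, fastica_core(Z))
    if (fit$converged) break
  }
  if (!fit$converged)
    warning("ICA did not converge after ", max_retries + 1, " attempts")
  S <- fit$W %*% Z
  A <- E %*% diag(sqrt(lam)) %*% t(fit$W)               # channel-space maps
  tt <- templates$template_topographies
  cors <- abs(stats::cor(t(tt), A))                     # 2 x n_pca
  pick1 <- which.max(cors[1, ])
  c2 <- cors[2, ]; c2[pick1] <- -Inf
  pick2 <- which.max(c2)
  rem <- c(pick1, pick2)
  Xclean <- Xc - A[, rem, drop = FALSE] %*% S[rem, , drop = FALSE] + mu
  out <- aperm(array(Xclean, dim = c(d[2], d[3], d[1])), c(3, 1, 2))
  res <- set_data(data, out)
  attr(res, "ica_report") <- list(removed = rem,
                                  template_correlation = cors[cbind(1:2, rem)],
                                  converged = fit$converged, iterations = fit$iter)
  res
}

#' Crop each trial to its final feedback window
#'
#' Keeps the last `length` seconds of every trial's feedback period (the
#' epoch is assumed to end at feedback offset). Trials with feedback shorter
#' than `length` are dropped and counted in the `window_report` attribute.
#'
#' @param data an `epoched_eeg` whose `trial_meta` has `feedback_duration`.
#' @param length window length in seconds (default 1).
#' @return cropped `epoched_eeg`.
#' @export
extract_analysis_window <- function(data, length = 1) {
  fs <- data$sampling_rate
  L <- round(length * fs)
  fb <- data$trial_meta$feedback_duration
  if (is.null(fb)) fb <- rep(n_samples(data) / fs, n_trials(data))
  keep <- fb >= length
  if (!any(keep)) stop("all trials shorter than the analysis window")
  ns <- n_samples(data)
  out <- data$data[keep, , (ns - L + 1):ns, drop = FALSE]
  res <- set_data(data, out, trial_meta = data$trial_meta[keep, , drop = FALSE])
  attr(res, "window_report") <- list(dropped = sum(!keep), kept = sum(keep))
  res
}

#' Automated variance-based trial rejection
#'
#' Replaces visual inspection: a trial is rejected when the robust z-score
#' (median/MAD across trials) of its log broadband variance exceeds the
#' threshold.
#'
#' @param data an `epoched_eeg` with at least 5 trials.
#' @param variance_z_threshold robust z threshold (default 3.5).
#' @return `epoched_eeg` with a `rejection_report` attribute.
#' @export
reject_noisy_trials <- function(data, variance_z_threshold = 3.5) {
  if (n_trials(data) < 5) stop("need at least 5 trials")
  v <- apply(data$data, 1, function(m) log(mean(m^2)))
  md <- median(v); s <- mad(v)
  z <- if (s > 0) (v - md) / s else rep(0, length(v))
  bad <- which(z > variance_z_threshold)
  if (length(bad) == n_trials(data)) stop("all trials rejected")
  keep <- setdiff(seq_len(n_trials(data)), bad)
  res <- set_data(data, data$data[keep, , , drop = FALSE],
                  trial_meta = data$trial_meta[keep, , drop = FALSE])
  attr(res, "rejection_report") <- list(rejected = bad, z = z,
                                        threshold = variance_z_threshold)
  res
}

#' Run the full preprocessing chain
#'
#' Fixed order: band-pass filter, resample, bad-channel interpolation,
#' common-average reference, ICA ocular removal, analysis-window extraction,
#' variance-based trial rejection.
#'
#' @param data an `epoched_eeg`.
#' @param low,high band-pass edges (default 1-100 Hz).
#' @param target_rate resampling target (skipped when already at or below).
#' @param bad bad channels to interpolate.
#' @param templates `ica_templates` (built from the montage when `NULL`).
#' @param n_pca PCA dimensionality for ICA.
#' @param window_length analysis window in seconds.
#' @param variance_z_threshold trial-rejection threshold.
#' @param seed ICA seed.
#' @return preprocessed `epoched_eeg` with a `preprocess_report` attribute.
#' @export
preprocess <- function(data, low = 1, high = 100, target_rate = 250,
                       bad = character(), templates = NULL, n_pca = 30,
                       window_length = 1, variance_z_threshold = 3.5,
                       seed = 1) {
  high <- min(high, 0.99 * data$sampling_rate / 2 - 1e-9)
  data <- bandpass_filter(data, low, high)
  if (target_rate < data$sampling_rate)
    data <- resample(data, target_rate)
  data <- interpolate_bad_channels(data, bad)
  data <- common_average_reference(data)
  if (is.null(templates)) templates <- make_ica_templates(data$montage)
  n_pca <- min(n_pca, n_channels(data))
  data <- remove_ocular_components(data, templates, n_pca = n_pca, seed = seed)
  ica_rep <- attr(data, "ica_report")
  data <- extract_analysis_window(data, window_length)
  win_rep <- attr(data, "window_report")
  data <- reject_noisy_trials(data, variance_z_threshold)
  rej_rep <- attr(data, "rejection_report")
  attr(data, "preprocess_report") <- list(ica = ica_rep, window = win_rep,
                                          rejection = rej_rep)
  data
}
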
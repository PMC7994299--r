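# DICS beamformer: band cross-spectral density, unit-gain spatial filters,
# source power maps, ROI centroid time courses.

#' Band-limited cross-spectral density
#'
#' Trial-averaged outer products of Hann-tapered Fourier coefficients over
#' all 1-Hz bins inside the band.
#'
#' @param data an `epoched_eeg` with at least 2 trials.
#' @param band numeric length-2 Hz interval (e.g. `c(9, 15)`).
#' @return object of class `csd`: `matrix` (channels x channels complex,
#'   Hermitian PSD), `band`, `n_trials`, and `fourier` (channels x bins x
#'   trials complex coefficients, for per-trial source power).
#' @export
compute_csd <- function(data, band) {
  d <- dim(data$data)
  if (d[1] < 2) stop("need at least 2 trials")
  fs <- data$sampling_rate
  ns <- d[3]
  if (ceiling(band[1]) > floor(band[2])) stop("empty band")
  freqs <- seq(ceiling(band[1]), floor(band[2]), by = 1)
  if (max(freqs) > fs / 2) stop("band exceeds Nyquist")
  bins <- round(freqs * ns / fs) + 1
  w <- hann_window(ns)
  m <- matrix(aperm(data$data, c(3, 1, 2)), nrow = ns)
  X <- stats::mvfft(m * w)[bins, , drop = FALSE]        # bins x (trials*channels)
  # reshape to channels x (bins*trials)
  A <- array(X, dim = c(length(bins), d[1], d[2]))
  Fc <- aperm(A, c(3, 1, 2))                            # channels x bins x trials
  Fm <- matrix(Fc, nrow = d[2])
  C <- (Fm %*% Conj(t(Fm))) / ncol(Fm)
  C <- (C + Conj(t(C))) / 2
  structure(list(matrix = C, band = band, n_trials = d[1], freqs = freqs,
                 fourier = Fc, channel_names = data$montage$channel_names),
            class = "csd")
}

#' DICS spatial filter at one grid point
#'
#' Unit-gain constrained minimum-variance filter
#' `A = (L' Cr^-1 L)^-1 L' Cr^-1` built from the real part of the
#' regularized CSD `Cr = Re(C) + lambda * (trace/nchan) * I`, reduced to the
#' dominant source orientation (largest eigenvalue of the 3x3 source power
#' matrix).
#'
#' @param csd a `csd`.
#' @param leadfield a `leadfield`.
#' @param grid_index grid point index.
#' @param lambda regularization as a fraction of mean sensor power
#'   (default 0.05).
#' @param orientation `"dominant"` (scalar filter, default) or `"vector"`
#'   (3 x channels).
#' @return filter matrix (1 x channels or 3 x channels) with attribute
#'   `"orientation"` (unit 3-vector) when reduced.
#' @export
dics_filter <- function(csd, leadfield, grid_index, lambda = 0.05,
                        orientation = c("dominant", "vector")) {
  orientation <- match.arg(orientation)
  C <- Re(csd$matrix)
  nch <- nrow(C)
  Cr <- C + lambda * (sum(diag(C)) / nch) * diag(nch)
  ev <- tryCatch(solve(Cr), error = function(e)
    stop("regularized CSD is singular; increase lambda"))
  L <- t(leadfield$gains[grid_index, , ])               # channels x 3
  M <- t(L) %*% ev %*% L
  if (rcond(M) < 1e-14) stop("singular L' C^-1 L at grid point ", grid_index)
  A3 <- solve(M, t(L) %*% ev)                           # 3 x channels
  if (orientation == "vector") return(A3)
  Q <- A3 %*% C %*% t(A3)
  u <- eigen((Q + t(Q)) / 2, symmetric = TRUE)$vectors[, 1]
  A <- matrix(u, 1) %*% A3
  attr(A, "orientation") <- u
  A
}

#' Source power map over the grid
#'
#' Power at each inside grid point through its DICS filter:
#' `p = A C A^H` with the dominant-orientation scalar filter. Per-trial maps
#' (mean over band bins of `|A F_t|^2`) are returned for statistics.
#'
#' Unit-gain beamformer power at a deep, low-gain grid point is noise
#' amplified by the inverse filter norm (the classic centre-of-head bias);
#' by default the map is therefore noise-normalized (the neural activity
#' index `A C A^H / (A A^H)`), which is flat for white sensor noise.
#'
#' @param csd a `csd` (provides both the filter CSD and the per-trial
#'   Fourier coefficients).
#' @param leadfield a `leadfield`.
#' @param lambda regularization fraction.
#' @param normalize divide by the filter norm (default `TRUE`).
#' @return object of class `source_power_map`: `power` (per grid point),
#'   `trial_power` (trials x grid points), `band`.
#' @export
source_power_map <- function(csd, leadfield, lambda = 0.05,
                             normalize = TRUE) {
  ng <- dim(leadfield$gains)[1]
  idx <- which(leadfield$inside_mask)
  C <- Re(csd$matrix)
  nch <- nrow(C)
  Cr <- C + lambda * (sum(diag(C)) / nch) * diag(nch)
  Ci <- solve(Cr)
  d <- dim(csd$fourier)                                 # channels x bins x trials
  Fm <- matrix(csd$fourier, nrow = d[1])
  pow <- rep(NA_real_, ng)
  tp <- matrix(NA_real_, d[3], ng)
  for (g in idx) {
    L <- t(leadfield$gains[g, , ])
    M <- t(L) %*% Ci %*% L
    A3 <- solve(M, t(L) %*% Ci)
    Q <- A3 %*% C %*% t(A3)
    u <- eigen((Q + t(Q)) / 2, symmetric = TRUE)$vectors[, 1]
    A <- matrix(u, 1) %*% A3
    nrm <- if (normalize) sum(A^2) else 1
    pow[g] <- max(0, as.numeric(Re(A %*% csd$matrix %*% Conj(t(A))))) / nrm
    s <- Mod(A %*% Fm)^2 / nrm                          # 1 x (bins*trials)
    tp[, g] <- colMeans(matrix(s, d[2], d[3]))
  }
  structure(list(power = pow, trial_power = tp, band = csd$band,
                 grid_positions = leadfield$grid_positions),
            class = "source_power_map")
}

#' Band-limited analytic source time courses at ROI centroids
#'
#' Applies the DICS filter of each ROI centroid (computed from the supplied
#' CSD — typically pooled over sessions so filters are common) to the sensor
#' time series band-passed to `band`, and forms the complex analytic signal
#' per trial via the Hilbert transform.
#'
#' @param data an `epoched_eeg`.
#' @param csd a `csd` used to build the filters.
#' @param leadfield a `leadfield`.
#' @param parcellation a `parcellation` with centroids selected.
#' @param band Hz interval for the band-pass.
#' @param lambda regularization fraction.
#' @return object of class `roi_timecourses`: `signal` (complex array
#'   rois x trials x samples), `band`, `sampling_rate`, `roi_names`.
#' @export
roi_timecourses <- function(data, csd, leadfield, parcellation, band,
                            lambda = 0.05) {
  cent <- parcellation$centroid_grid_index
  if (any(is.na(cent))) stop("centroids not selected")
  fs <- data$sampling_rate
  d <- dim(data$data)
  filt <- t(vapply(cent, function(g)
    as.numeric(dics_filter(csd, leadfield, g, lambda)), numeric(d[2])))
  # band-pass the sensor data (hard FFT mask edges consistent with the CSD band)
  bp <- apply_samplewise(data$data, function(m)
    fft_band_filter(m, fs, band[1] - 1, band[1], band[2], band[2] + 1))
  nroi <- length(cent)
  out <- array(complex(real = 0), dim = c(nroi, d[1], d[3]))
  for (tr in seq_len(d[1])) {
    src <- filt %*% matrix(bp[tr, , ], d[2], d[3])      # rois x samples
    for (r in seq_len(nroi)) out[r, tr, ] <- analytic_signal(src[r, ])
  }
  structure(list(signal = out, band = band, sampling_rate = fs,
                 roi_names = parcellation$roi_names),
            class = "roi_timecourses")
}
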
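test_that("band-pass filter meets its attenuation contract", {
  m <- fx_montage32()
  fs <- 1000
  ns <- 10000
  t <- seq_len(ns) / fs
  mk <- function(f) sin(2 * pi * f * t)
  arr <- array(0, c(3, 32, ns))
  arr[1, , ] <- matrix(mk(50), 32, ns, byrow = TRUE)
  arr[2, , ] <- matrix(mk(0.2), 32, ns, byrow = TRUE)
  arr[3, , ] <- matrix(mk(0.5), 32, ns, byrow = TRUE)
  f1 <- bandpass_filter(epoched_eeg(arr, fs, m), 1, 100)
  mid <- 2001:8000                           # steady-state (edge-free) span
  # in-band sinusoid preserved within 5%
  expect_equal(rms(f1$data[1, 1, mid]), rms(arr[1, 1, mid]), tolerance = 0.05)
  # 0.2 Hz drift attenuated >= 90%
  expect_lt(rms(f1$data[2, 1, mid]) / rms(arr[2, 1, mid]), 0.1)
  # >= 20 dB at low/2
  expect_lt(rms(f1$data[3, 1, mid]) / rms(arr[3, 1, mid]), 10^(-20 / 20))
  expect_error(bandpass_filter(epoched_eeg(arr, fs, m), 60, 40), "invalid band")
  expect_error(bandpass_filter(epoched_eeg(arr, fs, m), 1, 600), "invalid band")
})

test_that("resampling preserves in-band content and sample arithmetic", {
  m <- fx_montage32()
  fs <- 1000
  sig <- sin(2 * pi * 10 * seq_len(4000) / fs)
  ep <- signal_epochs(m, "Cz", sig, fs = fs)
  r <- resample(ep, 250)
  expect_equal(dim(r$data)[3], 1000)
  expect_equal(r$sampling_rate, 250)
  i <- match("Cz", m$channel_names)
  expect_equal(rms(r$data[1, i, ]), rms(sig), tolerance = 0.02)
  expect_error(resample(r, 1000), "upsampling")
  expect_error(resample(ep, 333), "divide")
})

test_that("spherical-spline interpolation reproduces constants and beats
           nearest-neighbour averaging on a dipolar field", {
  m <- fx_montage32()
  ep <- epoched_eeg(array(5, c(1, 32, 50)), 250, m)
  expect_identical(interpolate_bad_channels(ep, character()), ep)
  ip <- interpolate_bad_channels(ep, "C3")
  i <- match("C3", m$channel_names)
  expect_equal(ip$data[1, i, ], rep(5, 50), tolerance = 0.01)
  # good channels untouched
  expect_identical(ip$data[1, -i, ], ep$data[1, -i, ])
  # dipolar fields: mean spline error < mean 4-nearest-neighbour error
  nb <- match(montage_neighbors(m, "C3", 4), m$channel_names)
  set.seed(7)
  errs <- t(replicate(30, {
    v <- restalpha:::sphere_dipole_potential(runif(3, -0.4, 0.4), rnorm(3),
                                             m$positions3d)
    epd <- epoched_eeg(array(v, c(1, 32, 1)), 250, m)
    ipd <- interpolate_bad_channels(epd, "C3")
    c(abs(ipd$data[1, i, 1] - v[i]), abs(mean(v[nb]) - v[i]))
  }))
  expect_lt(mean(errs[, 1]), mean(errs[, 2]))
  expect_error(interpolate_bad_channels(ep, m$channel_names[1:10]),
               "too many")
})

test_that("common average reference zeroes channel means and is idempotent", {
  m <- fx_montage32()
  ep <- noise_epochs(m, seed = 4)
  cc <- common_average_reference(ep)
  expect_lt(max(abs(apply(cc$data, c(1, 3), mean))), 1e-9)
  expect_equal(common_average_reference(cc)$data, cc$data, tolerance = 1e-12)
  # commutes with spherical-spline interpolation on a synthetic field
  ip_then_car <- common_average_reference(interpolate_bad_channels(ep, "C3"))
  # (interpolation uses only good channels, so referencing after equals
  # referencing the interpolated set)
  expect_lt(max(abs(apply(ip_then_car$data, c(1, 3), mean))), 1e-9)
})

test_that("template ICA removes an injected blink and perturbs clean data
           little", {
  set.seed(31)
  m <- fx_montage32(); fs <- 250; ntr <- 6; ns <- 500
  tmpl <- make_ica_templates(m)
  expect_equal(dim(tmpl$template_topographies), c(2L, 32L))
  expect_equal(rowSums(tmpl$template_topographies^2), c(blink = 1, eog = 1))
  hd <- fx_head32()
  post <- which(hd$leadfield$grid_positions[, 2] < -0.2)
  G <- vapply(1:10, function(i) {
    o <- rnorm(3); o <- o / sqrt(sum(o^2))
    as.numeric(t(hd$leadfield$gains[sample(post, 1), , ]) %*% o)
  }, numeric(32))
  burst <- function(lo, hi) {
    e <- exp(0.9 * restalpha:::one_over_f_noise(ns, 1, fs))
    4 * restalpha:::narrowband_noise(ns, lo, hi, fs) * e
  }
  arr <- array(0, c(ntr, 32, ns))
  for (tr in seq_len(ntr)) {
    S <- vapply(1:10, function(i) burst(3 + 3 * i, 6 + 3 * i), numeric(ns))
    arr[tr, , ] <- t(S %*% t(G)) + matrix(rnorm(32 * ns, 0, 0.5), 32)
  }
  blinktc <- matrix(0, ntr, ns)
  blink <- array(0, c(ntr, 32, ns))
  pulse <- restalpha:::hann_window(75)
  for (tr in seq_len(ntr)) {
    s <- rep(0, ns)
    for (b in sample(ns - 80, 3)) s[b:(b + 74)] <- s[b:(b + 74)] + 40 * pulse
    blinktc[tr, ] <- s
    blink[tr, , ] <- outer(tmpl$template_topographies["blink", ], s)
  }
  ep <- epoched_eeg(arr + blink, fs, m)
  cl <- suppressWarnings(remove_ocular_components(ep, tmpl, n_pca = 20,
                                                  seed = 2))
  rep <- attr(cl, "ica_report")
  expect_length(rep$removed, 2)
  # the blink component is found with a near-perfect topography match
  expect_gt(max(rep$template_correlation), 0.9)
  # variance locked to the known blink time course drops >= 80% frontally
  fidx <- which(abs(tmpl$template_topographies["blink", ]) > 0.2)
  bb <- ba <- 0
  for (tr in seq_len(ntr)) {
    tc <- blinktc[tr, ] - mean(blinktc[tr, ]); den <- sum(tc^2)
    for (chn in fidx) {
      bb <- bb + (sum((arr[tr, chn, ] + blink[tr, chn, ]) * tc) / den)^2
      ba <- ba + (sum(cl$data[tr, chn, ] * tc) / den)^2
    }
  }
  expect_gt(1 - ba / bb, 0.8)
  # clean data: removing the two best-matching components perturbs little
  # (mean per-channel correlation; a strict per-channel floor is not
  # attainable when two components must always be removed — see vignette)
  ep2 <- epoched_eeg(arr, fs, m)
  cl2 <- suppressWarnings(remove_ocular_components(ep2, tmpl, n_pca = 20,
                                                   seed = 2))
  cors <- vapply(1:32, function(chn)
    cor(as.vector(cl2$data[, chn, ]), as.vector(arr[, chn, ])), numeric(1))
  expect_gt(mean(cors), 0.95)
  expect_gt(min(cors), 0.7)
  # dimensionality contract: n_pca components, exactly two removed
  expect_error(remove_ocular_components(ep, tmpl, n_pca = 40), "exceeds")
  expect_error(remove_ocular_components(ep, tmpl, n_pca = 20, n_ic = 10),
               "must equal")
})

test_that("analysis-window extraction crops the final feedback second", {
  m <- fx_montage32()
  fs <- 250
  ep <- noise_epochs(m, n_trials = 5, n_samples = 1500, fs = fs, seed = 5)
  ep$trial_meta$feedback_duration <- c(6, 3, 2, 0.5, 6)
  w <- extract_analysis_window(ep, 1)
  expect_equal(dim(w$data)[1], 4)            # 0.5 s trial dropped
  expect_equal(attr(w, "window_report")$dropped, 1)
  expect_equal(dim(w$data)[3], 250)
  expect_equal(w$data[1, 1, ], ep$data[1, 1, 1251:1500])
})

test_that("variance-based trial rejection flags the constructed outlier", {
  m <- fx_montage32()
  ep <- noise_epochs(m, n_trials = 10, seed = 6)
  expect_identical(dim(reject_noisy_trials(ep, Inf)$data), dim(ep$data))
  expect_identical(dim(reject_noisy_trials(ep, 5)$data)[1], 10L)
  ep$data[7, , ] <- ep$data[7, , ] * 10     # 100x variance
  r <- reject_noisy_trials(ep, 3.5)
  expect_equal(attr(r, "rejection_report")$rejected, 7)
  expect_error(reject_noisy_trials(noise_epochs(m, n_trials = 3), 3.5),
               "at least 5")
})
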
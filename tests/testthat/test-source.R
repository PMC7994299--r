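# Simulate an oscillating dipole at a known grid point and return epochs.
dipole_epochs <- function(hd, g, snr = 10, ntr = 30, ns = 250, fs = 250,
                          seed = 1, ori = c(0, 0, 1), band = c(9, 15)) {
  set.seed(seed)
  nch <- length(hd$montage$channel_names)
  gv <- as.numeric(t(hd$leadfield$gains[g, , ]) %*% ori)
  arr <- array(0, c(ntr, nch, ns))
  for (tr in seq_len(ntr)) {
    s <- restalpha:::narrowband_noise(ns, band[1], band[2], fs)
    arr[tr, , ] <- gv %o% s +
      matrix(rnorm(nch * ns, 0, sd(gv) / sqrt(snr)), nch)
  }
  epoched_eeg(arr, fs, hd$montage)
}

test_that("cross-spectral density is Hermitian, band-restricted and rank
           reflects shared signals", {
  hd <- fx_head32()
  ep <- dipole_epochs(hd, 40, seed = 51)
  csd <- compute_csd(ep, c(9, 15))
  expect_equal(length(csd$freqs), 7)          # 9..15 at 1 Hz: 7 bins
  expect_lt(max(abs(csd$matrix - Conj(t(csd$matrix)))), 1e-10)
  ev <- eigen(csd$matrix, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(Re(ev)), -1e-8 * sum(Re(ev)))
  # two channels carrying the identical signal: coherence 1
  m <- fx_montage32()
  set.seed(52)
  arr <- array(rnorm(4 * 32 * 250, 0, 0.01), c(4, 32, 250))
  s <- restalpha:::narrowband_noise(1000, 9, 15, 250)
  arr[, 1, ] <- matrix(s, 4, 250, byrow = TRUE)
  arr[, 2, ] <- matrix(s, 4, 250, byrow = TRUE)
  c2 <- compute_csd(epoched_eeg(arr, 250, m), c(9, 15))
  coh <- Mod(c2$matrix[1, 2]) /
    sqrt(Re(c2$matrix[1, 1]) * Re(c2$matrix[2, 2]))
  expect_gt(coh, 0.999)
  # independent channels: off-diagonal coherence decays with trials
  dec <- vapply(c(6, 60), function(ntr) {
    set.seed(53)
    a <- array(rnorm(ntr * 32 * 250), c(ntr, 32, 250))
    cc <- compute_csd(epoched_eeg(a, 250, m), c(9, 15))
    d <- Mod(cc$matrix); mean(d[upper.tri(d)]) / mean(diag(d))
  }, numeric(1))
  expect_lt(dec[2], dec[1])
  expect_error(compute_csd(ep, c(15.5, 15.7)), "empty band")
})

test_that("DICS filter satisfies unit gain and matches the constrained
           least-squares oracle", {
  hd <- fx_head32()
  ep <- dipole_epochs(hd, 40, seed = 54)
  csd <- compute_csd(ep, c(9, 15))
  A3 <- dics_filter(csd, hd$leadfield, 40, orientation = "vector")
  L <- t(hd$leadfield$gains[40, , ])
  expect_equal(unname(A3 %*% L), diag(3), tolerance = 1e-8)
  # oracle: solve the KKT system of min tr(A C A') s.t. A L = I directly
  C <- Re(csd$matrix)
  nch <- nrow(C)
  Cr <- C + 0.05 * (sum(diag(C)) / nch) * diag(nch)
  kkt <- rbind(cbind(2 * Cr, L), cbind(t(L), matrix(0, 3, 3)))
  rhs <- rbind(matrix(0, nch, 3), diag(3))
  sol <- solve(kkt, rhs)
  expect_equal(unname(t(sol[1:nch, ])), unname(A3), tolerance = 1e-6)
  # rank-deficient CSD without regularization errors
  bad <- csd
  bad$matrix <- matrix(0, nch, nch); bad$matrix[1, 1] <- 1
  expect_error(dics_filter(bad, hd$leadfield, 40, lambda = 0), "singular")
})

test_that("source power maps localize, stay non-negative and scale
           quadratically", {
  hd <- fx_head32()
  ep <- dipole_epochs(hd, 40, snr = 10, seed = 55)
  csd <- compute_csd(ep, c(9, 15))
  pm <- source_power_map(csd, hd$leadfield)
  expect_true(all(pm$power >= 0))
  expect_equal(dim(pm$trial_power), c(30, 150))
  err <- sqrt(sum((hd$leadfield$grid_positions[which.max(pm$power), ] -
                     hd$leadfield$grid_positions[40, ])^2))
  expect_lte(err, hd$leadfield$spacing + 1e-9)
  # scaling data by c scales the map by c^2
  ep2 <- ep; ep2$data <- ep2$data * 3
  pm2 <- source_power_map(compute_csd(ep2, c(9, 15)), hd$leadfield)
  expect_equal(pm2$power, 9 * pm$power, tolerance = 1e-8)
  # two well-separated dipoles produce local maxima near both
  pos <- hd$leadfield$grid_positions
  g1 <- 40; g2 <- which.max(colSums((t(pos) - pos[g1, ])^2))
  set.seed(56)
  gv1 <- as.numeric(t(hd$leadfield$gains[g1, , ]) %*% c(0, 0, 1))
  gv2 <- as.numeric(t(hd$leadfield$gains[g2, , ]) %*% c(1, 0, 0))
  gv1 <- gv1 / sqrt(sum(gv1^2)); gv2 <- gv2 / sqrt(sum(gv2^2))
  arr <- array(0, c(30, 32, 250))
  for (tr in 1:30) {
    arr[tr, , ] <- gv1 %o% restalpha:::narrowband_noise(250, 9, 15, 250) +
      gv2 %o% restalpha:::narrowband_noise(250, 9, 15, 250) +
      matrix(rnorm(32 * 250, 0, sd(gv1) / 3), 32)
  }
  pm3 <- source_power_map(compute_csd(epoched_eeg(arr, 250, hd$montage),
                                      c(9, 15)), hd$leadfield)
  near <- function(g) which(colSums((t(pos) - pos[g, ])^2) <=
                              (1.5 * hd$leadfield$spacing)^2)
  top10 <- order(-pm3$power)[1:10]
  expect_true(any(top10 %in% near(g1)))
  expect_true(any(top10 %in% near(g2)))
  # white noise only: no point dominates the map
  set.seed(57)
  nz <- epoched_eeg(array(rnorm(30 * 32 * 250), c(30, 32, 250)), 250,
                    hd$montage)
  pmn <- source_power_map(compute_csd(nz, c(9, 15)), hd$leadfield)
  expect_lt(max(pmn$power) / median(pmn$power), 3)
})

test_that("ROI time courses recover an injected centroid source", {
  hd <- fx_head32()
  parc <- hd$parcellation
  roi <- 11
  g <- parc$centroid_grid_index[roi]
  set.seed(58)
  fs <- 250; ntr <- 10; ns <- 250
  gv <- as.numeric(t(hd$leadfield$gains[g, , ]) %*% c(0, 1, 0))
  inj <- matrix(0, ntr, ns)
  arr <- array(0, c(ntr, 32, ns))
  for (tr in seq_len(ntr)) {
    s <- restalpha:::narrowband_noise(ns, 9, 15, fs)
    inj[tr, ] <- s
    arr[tr, , ] <- gv %o% s + matrix(rnorm(32 * ns, 0, sd(gv) / sqrt(10)), 32)
  }
  ep <- epoched_eeg(arr, fs, hd$montage)
  csd <- compute_csd(ep, c(9, 15))
  tc <- roi_timecourses(ep, csd, hd$leadfield, parc, c(9, 15))
  expect_equal(dim(tc$signal), c(90, ntr, ns))
  r <- abs(cor(as.vector(Re(tc$signal[roi, , ])), as.vector(inj)))
  expect_gt(r, 0.8)
  # all-zero data gives all-zero time courses (filters from the real csd)
  z <- ep; z$data[] <- 0
  tcz <- roi_timecourses(z, csd, hd$leadfield, parc, c(9, 15))
  expect_equal(max(Mod(tcz$signal)), 0)
})
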
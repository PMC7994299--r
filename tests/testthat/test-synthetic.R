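small_cfg <- function(seed = 11, ...) {
  sim_config(n_subjects_per_group = 3, n_trials_per_session = 6,
             n_channels = 32, n_grid = 100, seed = seed, ...)
}

test_that("configuration validation enforces the stated invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_subjects_per_group = 0), "counts")
  expect_error(sim_config(rho_pvc = 1), "rho")
  expect_error(sim_config(effect_band = c(0.5, 15)), "effect_band")
  expect_error(sim_config(effect_band = c(15, 9)), "effect_band")
})

test_that("identical configurations give bit-identical cohorts", {
  co1 <- simulate_cohort(small_cfg())
  co2 <- simulate_cohort(small_cfg())
  expect_identical(co1$subjects[[2]]$sessions$last$data,
                   co2$subjects[[2]]$sessions$last$data)
  expect_identical(co1$behavior, co2$behavior)
  expect_identical(co1$ground_truth, co2$ground_truth)
  # a different seed changes the data
  co3 <- simulate_cohort(small_cfg(seed = 12))
  expect_false(identical(co1$subjects[[1]]$sessions$first$data,
                         co3$subjects[[1]]$sessions$first$data))
})

test_that("ground truth references valid indices and the coupled subgraph
           is connected with 10 edges", {
  co <- simulate_cohort(small_cfg(), eeg = FALSE)
  gt <- co$ground_truth
  expect_true(all(gt$target_grid_points %in% seq_len(100)))
  expect_true(all(gt$target_channels %in% seq_len(32)))
  expect_equal(nrow(gt$target_edges), 10)
  expect_true(all(gt$target_edges >= 1 & gt$target_edges <= 90))
  expect_true(all(gt$target_edges[, 1] < gt$target_edges[, 2]))
  g <- igraph::graph_from_edgelist(
    matrix(match(gt$target_edges, gt$coupled_rois), ncol = 2),
    directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
  expect_length(gt$subject_alpha_change, 6)
})

test_that("sensor spectra carry the generative 1/f slope and the injected
           alpha is measurable at the designated sensors", {
  cfg <- sim_config(n_subjects_per_group = 1, n_trials_per_session = 30,
                    n_channels = 32, n_grid = 100, artifact_rate = 0,
                    noise_1f_exponent = 1, seed = 13)
  co <- simulate_cohort(cfg)
  sp <- compute_power_spectrum(co$subjects[[1]]$sessions$first,
                               average = TRUE)
  psd <- colMeans(sp$power)
  fr <- 2:40
  keep <- !(fr %in% 8:16)                 # exclude the alpha bump
  slope <- -coef(lm(log(psd[fr][keep]) ~ log(fr[keep])))[2]
  expect_lt(abs(slope - 1), 0.3)
  # alpha effect band power at target sensors well above the 1/f floor
  tc <- co$ground_truth$target_channels
  band <- mean(sp$power[tc, 9:15])
  floor_ <- mean(sp$power[tc, c(4:6, 18:20)])
  expect_gt(band / floor_, 3)
})

test_that("interaction t-statistics are t-distributed under the null", {
  # KS check on one fixed element's t across replicate null cohorts
  montage <- make_montage(32)
  h <- make_leadfield(montage, 100, seed = 7)
  hd <- list(montage = montage, leadfield = h$leadfield,
             parcellation = h$parcellation)
  tvals <- vapply(1:60, function(r) {
    cfg <- sim_config(n_subjects_per_group = 5, n_trials_per_session = 4,
                      n_channels = 32, n_grid = 100, power_effect_size = 0,
                      coupling_delta = 0, artifact_rate = 0, seed = 900 + r)
    co <- simulate_cohort(cfg, head = hd)
    im <- cohort_interaction_maps(co)
    element_t_map(im$values, im$group)$t[330]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(tvals, stats::pt, df = 8))
  expect_gt(ks$p.value, 0.01)
})

test_that("behaviour tables are consistent with the EEG trial outcomes and
          the copula links behaviour to the alpha latent", {
  co <- simulate_cohort(small_cfg())
  beh <- co$behavior
  expect_true(all(beh$hits + beh$misses + beh$timeouts == 6))
  for (i in seq_along(co$subjects)) {
    s <- co$subjects[[i]]
    for (ss in c("first", "last")) {
      counts <- table(factor(s$sessions[[ss]]$trial_meta$outcome,
                             levels = c("hit", "miss", "timeout")))
      row <- beh[beh$subject == s$id & beh$session == ss, ]
      expect_equal(unname(counts["hit"]), row$hits, ignore_attr = TRUE)
      expect_equal(unname(counts["timeout"]), row$timeouts,
                   ignore_attr = TRUE)
    }
  }
  # copula: generative correlation recovered at cohort scale
  cfg <- sim_config(n_subjects_per_group = 400, rho_minutes = 0.6,
                    rho_pvc = 0, seed = 14)
  sb <- simulate_behavior(cfg)
  w <- sb$behavior[sb$behavior$session == "first", ]
  u <- sb$latents$alpha_change[match(w$subject, sb$latents$subject)]
  expect_equal(cor(u, w$minutes), 0.6, tolerance = 0.08)
})

test_that("coupled-pair generator yields envelope correlation increasing in
           the mixing weight", {
  set.seed(15)
  r_lo <- mean(replicate(15, {
    p <- make_coupled_pair(8000, 0.2)
    envelope_correlation(p[1, ], p[2, ])
  }))
  r_hi <- mean(replicate(15, {
    p <- make_coupled_pair(8000, 0.8)
    envelope_correlation(p[1, ], p[2, ])
  }))
  expect_gt(r_hi, r_lo + 0.1)
  expect_error(make_coupled_pair(1000, 1.2), "weight")
})

test_that("cohorts round-trip through the plain-text dataset format", {
  co <- simulate_cohort(small_cfg())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "behavior.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  ep <- read_epochs(file.path(dir, co$subjects[[1]]$id, "first"))
  expect_equal(ep$data, co$subjects[[1]]$sessions$first$data,
               tolerance = 1e-6)
  expect_equal(ep$trial_meta$outcome,
               co$subjects[[1]]$sessions$first$trial_meta$outcome)
})
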
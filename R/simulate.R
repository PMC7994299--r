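# Synthetic cohort generator with machine-readable ground truth.
#
# The generative world, fixed once:
#  * sources: broadband 1/f background processes at random grid points plus
#    band-limited alpha oscillators (FFT-masked Gaussian noise — amplitude-
#    modulated narrowband noise, not sinusoids) at designated grid points,
#    projected to sensors through the spherical-head leadfield; pink sensor
#    noise and stereotyped frontal eyeblink/EOG transients on top.
#  * power effect: per-subject log alpha-power change at the target grid
#    points is sigma_w * (z_i + m_g), z_i ~ N(0,1), with m_g =
#    power_effect_size in the MBSR group and 0 in controls, so the
#    standardized group x session mean difference at the sources equals
#    power_effect_size exactly. sigma_w = 0.35 (typical between-session log
#    power drift).
#  * envelope coupling: sources at the centroids of a fixed 10-edge
#    connected ROI subgraph share per-edge log-normal envelope factors with
#    mixing weight w; adjacent members correlate ~ w^2. w shifts by
#    -/+ coupling_delta/2 across sessions in the MBSR/control group
#    respectively (MBSR decreases, controls increase) around w0 = 0.4.
#  * behaviour: a Gaussian copula ties practice minutes and the logit-scale
#    PVC session change to the standardized alpha change at rho_minutes and
#    rho_pvc; hit/miss/timeout counts are drawn binomially so PVC is exactly
#    computable from counts, and the EEG trial outcomes tabulate to the
#    same counts.

#' Simulation configuration
#'
#' Defaults encode the study-scale world: 31 subjects per group (62 total),
#' 60 trials per session, 64 channels at 250 Hz, 1-s analysis epochs, a
#' 9-15 Hz effect band, generative neural-behavioural correlations 0.36
#' (practice minutes) and 0.37 (PVC change), and a standardized power
#' interaction effect of 1.5 at the target sources.
#'
#' @param n_subjects_per_group,n_trials_per_session,n_channels counts.
#' @param sampling_rate Hz. @param epoch_length seconds.
#' @param n_grid source grid points (>= 90).
#' @param effect_band Hz interval of the injected alpha effect.
#' @param power_effect_size standardized group x session log-power effect.
#' @param coupling_delta change in envelope mixing weight across sessions.
#' @param rho_minutes,rho_pvc generative correlations (|rho| < 1).
#' @param noise_1f_exponent spectral slope of background and sensor noise.
#' @param sensor_noise_sd sensor noise amplitude (microvolts).
#' @param artifact_rate eyeblinks per minute.
#' @param seed master seed; identical configs give bit-identical cohorts.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects_per_group = 31, n_trials_per_session = 60,
                       n_channels = 64, sampling_rate = 250,
                       epoch_length = 1.0, n_grid = 400,
                       effect_band = c(9, 15), power_effect_size = 1.5,
                       coupling_delta = 0.2, rho_minutes = 0.36,
                       rho_pvc = 0.37, noise_1f_exponent = 1.0,
                       sensor_noise_sd = 2, artifact_rate = 10, seed = 1,
                       sigma_w = 0.45, sigma_b = 0.3, w0 = 0.4, env_sd = 0.4,
                       alpha_amp = 3, bg_amp = 1.5, n_bg = 30,
                       timeout_prob = 0.15) {
  cfg <- list(n_subjects_per_group = n_subjects_per_group,
              n_trials_per_session = n_trials_per_session,
              n_channels = n_channels, sampling_rate = sampling_rate,
              epoch_length = epoch_length, n_grid = n_grid,
              effect_band = effect_band,
              power_effect_size = power_effect_size,
              coupling_delta = coupling_delta, rho_minutes = rho_minutes,
              rho_pvc = rho_pvc, noise_1f_exponent = noise_1f_exponent,
              sensor_noise_sd = sensor_noise_sd, artifact_rate = artifact_rate,
              seed = seed,
              # world constants (defaults documented in the methods vignette)
              sigma_w = sigma_w, sigma_b = sigma_b, w0 = w0, env_sd = env_sd,
              alpha_amp = alpha_amp, bg_amp = bg_amp, n_bg = n_bg,
              timeout_prob = timeout_prob)
  counts <- c("n_subjects_per_group", "n_trials_per_session", "n_channels",
              "n_grid")
  if (any(unlist(cfg[counts]) < 1)) stop("counts must be >= 1")
  if (abs(cfg$rho_minutes) >= 1 || abs(cfg$rho_pvc) >= 1)
    stop("|rho| must be < 1")
  if (cfg$effect_band[1] < 1 || cfg$effect_band[2] > 50 ||
      diff(cfg$effect_band) <= 0)
    stop("effect_band must lie within [1, 50]")
  structure(cfg, class = "sim_config")
}

# Subject-level latent draws: standard-normal z, log-power change u, and
# copula-linked behavioural latents.
draw_latents <- function(cfg, boost = 1) {
  n <- cfg$n_subjects_per_group
  group <- rep(c("MBSR", "control"), each = n)
  z <- rnorm(2 * n)
  m_g <- ifelse(group == "MBSR", boost * cfg$power_effect_size, 0)
  u <- cfg$sigma_w * (z + m_g)
  c_std <- as.numeric(scale(u))
  mz <- cfg$rho_minutes * c_std + sqrt(1 - cfg$rho_minutes^2) * rnorm(2 * n)
  pz <- cfg$rho_pvc * c_std + sqrt(1 - cfg$rho_pvc^2) * rnorm(2 * n)
  data.frame(subject = sprintf("S%02d", seq_len(2 * n)), group = group,
             z = z, alpha_change = u, minutes_z = mz, pvc_z = pz,
             stringsAsFactors = FALSE)
}

# Behaviour table from latents: binomial counts per session plus practice
# minutes. PVC change spread on the logit scale is 0.7 SD (see vignette).
generate_behavior <- function(cfg, lat) {
  ntr <- cfg$n_trials_per_session
  n <- nrow(lat)
  logit_first <- qlogis(0.62) + 0.4 * rnorm(n)
  dlogit <- ifelse(lat$group == "MBSR", 0.5, 0.15) + 0.7 * lat$pvc_z
  p <- cbind(first = plogis(logit_first), last = plogis(logit_first + dlogit))
  minutes <- pmax(0, 400 + 150 * lat$minutes_z)
  rows <- list()
  for (i in seq_len(n)) {
    for (s in c("first", "last")) {
      to <- rbinom(1, ntr, cfg$timeout_prob)
      h <- rbinom(1, ntr - to, p[i, s])
      rows[[length(rows) + 1]] <- data.frame(
        subject = lat$subject[i], group = lat$group[i], session = s,
        hits = h, misses = ntr - to - h, timeouts = to,
        minutes = minutes[i], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate the behaviour table alone
#'
#' Draws the subject latents and the behaviour table (hit/miss/timeout
#' counts and practice minutes) without generating EEG — the inexpensive
#' path for behavioural-recovery checks.
#'
#' @param config a `sim_config`.
#' @return list `behavior` (data.frame), `latents` (with
#'   `alpha_change`, the per-subject latent log alpha-power change).
#' @param boost internal scaling of the group effect used by
#'   [simulate_cohort()] to deliver the standardized effect at the target
#'   sensors (leadfield dilution compensation); leave at 1 for
#'   behaviour-only simulation.
#' @export
simulate_behavior <- function(config, boost = 1) {
  with_seed(derive_seed(config$seed, "behavior"), {
    lat <- draw_latents(config, boost)
    list(behavior = generate_behavior(config, lat), latents = lat)
  })
}

# Fixed structural targets given a head model: 6 frontal target grid points,
# the 10-edge coupled ROI subgraph among frontolimbic networks, and the
# expected suprathreshold sensor elements.
define_targets <- function(cfg, lf, parc) {
  pos <- lf$grid_positions
  anchor <- c(0, 0.5, 0.35)
  d <- colSums((t(pos) - anchor)^2)
  target_grid <- order(d)[1:10]
  post <- colSums((t(pos) - c(0, -0.5, 0.35))^2)
  distractor_grid <- order(post)[1:6]
  fl <- which(parc$network_of_roi %in% c("LIM", "DMN", "FPN"))
  mem <- fl[1:8]
  local_edges <- rbind(cbind(1:7, 2:8), c(1, 4), c(3, 6), c(5, 8))
  target_edges <- cbind(mem[local_edges[, 1]], mem[local_edges[, 2]])
  target_edges <- t(apply(target_edges, 1, sort))
  # alpha-source dipole orientations are anatomy: fixed per cohort and
  # shared between the generator and the expected-sensor computation
  src_grid <- c(target_grid, distractor_grid,
                parc$centroid_grid_index[mem])
  ori <- with_seed(derive_seed(cfg$seed, "orient"), {
    o <- matrix(rnorm(3 * length(src_grid)), ncol = 3)
    o / sqrt(rowSums(o^2))
  })
  # non-target oscillators (posterior distractors, coupled centroids) run at
  # reduced amplitude so the designated channels carry the injected effect
  src_amp <- c(rep(1, length(target_grid)),
               rep(0.5, length(distractor_grid) + length(mem)))
  # expected-suprathreshold sensors: channels where the target sources
  # dominate realized band power (largest target share of alpha gain)
  nch <- dim(lf$gains)[3]
  G <- vapply(seq_along(src_grid), function(i)
    src_amp[i] * as.numeric(t(lf$gains[src_grid[i], , ]) %*% ori[i, ]),
    numeric(nch))
  share <- rowSums(G[, seq_along(target_grid), drop = FALSE]^2) /
    pmax(rowSums(G^2), 1e-300)
  target_channels <- order(-share)[1:8]
  target_share <- mean(share[target_channels])
  freqs <- seq(ceiling(cfg$effect_band[1]), floor(cfg$effect_band[2]))
  elements <- expand.grid(channel = sort(target_channels), freq = freqs)
  list(target_grid_points = target_grid, distractor_grid = distractor_grid,
       coupled_rois = mem, target_edges = target_edges,
       alpha_src_grid = src_grid, alpha_src_ori = ori, alpha_src_amp = src_amp,
       target_channels = sort(target_channels), target_share = target_share,
       target_sensor_freq_elements = elements)
}

# One subject-session EEG: sources -> sensors -> epochs.
simulate_session_eeg <- function(cfg, head, targets, subject, group, session,
                                 log_power_delta, baseline_logamp, outcomes,
                                 seed) {
  with_seed(seed, {
    fs <- cfg$sampling_rate
    ns <- round(cfg$epoch_length * fs)
    ntr <- cfg$n_trials_per_session
    Tn <- ns * ntr
    lf <- head$leadfield
    nch <- dim(lf$gains)[3]

    src_grid <- targets$alpha_src_grid
    n_alpha <- length(src_grid)
    bg_grid <- sample.int(cfg$n_grid, cfg$n_bg)
    ori_bg <- matrix(rnorm(3 * cfg$n_bg), ncol = 3)
    ori_bg <- ori_bg / sqrt(rowSums(ori_bg^2))
    all_grid <- c(src_grid, bg_grid)
    ori <- rbind(targets$alpha_src_ori, ori_bg)
    G <- vapply(seq_along(all_grid), function(i)
      as.numeric(t(lf$gains[all_grid[i], , ]) %*% ori[i, ]), numeric(nch))

    # alpha carriers: band-limited noise, continuous across the session
    carriers <- narrowband_noise(Tn, cfg$effect_band[1], cfg$effect_band[2],
                                 fs, m = n_alpha)
    # per-trial log-normal envelopes with edge-shared factors
    w <- cfg$w0 + ifelse(group == "MBSR", 1, -1) *
      ifelse(session == "first", 1, -1) * cfg$coupling_delta / 2
    w <- min(max(w, 0), 0.57)
    mem <- targets$coupled_rois
    n_noncoupled <- n_alpha - length(mem)   # power targets + distractors
    k_i <- vapply(seq_along(mem), function(i)
      sum(targets$target_edges == mem[i]), numeric(1))
    Ze <- matrix(rnorm(nrow(targets$target_edges) * ntr), ntr)
    logenv <- matrix(rnorm(n_alpha * ntr), ntr)          # own factors
    for (i in seq_along(mem)) {
      inc <- which(targets$target_edges[, 1] == mem[i] |
                     targets$target_edges[, 2] == mem[i])
      col <- n_noncoupled + i
      logenv[, col] <- w * rowSums(Ze[, inc, drop = FALSE]) +
        sqrt(max(0, 1 - w^2 * k_i[i])) * logenv[, col]
    }
    env <- exp(cfg$env_sd * logenv - cfg$env_sd^2 / 2)
    env_full <- env[rep(seq_len(ntr), each = ns), , drop = FALSE]

    # amplitudes: power effect at target points, stable elsewhere
    n_tgt <- length(targets$target_grid_points)
    amp <- cfg$alpha_amp * targets$alpha_src_amp
    amp[1:n_tgt] <- amp[1:n_tgt] *
      exp((baseline_logamp + if (session == "last") log_power_delta else 0) / 2)
    X_alpha <- carriers * env_full * matrix(amp, Tn, n_alpha, byrow = TRUE)

    X_bg <- cfg$bg_amp * one_over_f_noise(Tn, cfg$noise_1f_exponent, fs,
                                          m = cfg$n_bg)
    Y <- cbind(X_alpha, X_bg) %*% t(G)                   # samples x channels
    Y <- Y + cfg$sensor_noise_sd *
      one_over_f_noise(Tn, cfg$noise_1f_exponent, fs, m = nch)

    # ocular transients
    tmpl <- make_ica_templates(head$montage)$template_topographies
    n_blink <- rpois(1, cfg$artifact_rate * Tn / fs / 60)
    if (n_blink > 0) {
      pulse <- hann_window(round(0.3 * fs))
      for (b in seq_len(n_blink)) {
        t0 <- sample.int(Tn - length(pulse), 1)
        amp_b <- 40 * (0.8 + 0.4 * runif(1))
        idx <- t0:(t0 + length(pulse) - 1)
        Y[idx, ] <- Y[idx, ] + amp_b * pulse %o% tmpl["blink", ]
      }
    }
    n_eog <- rpois(1, cfg$artifact_rate / 2 * Tn / fs / 60)
    if (n_eog > 0) {
      pulse <- hann_window(round(0.5 * fs))
      for (b in seq_len(n_eog)) {
        t0 <- sample.int(Tn - length(pulse), 1)
        idx <- t0:(t0 + length(pulse) - 1)
        Y[idx, ] <- Y[idx, ] + 30 * sample(c(-1, 1), 1) * pulse %o% tmpl["eog", ]
      }
    }

    arr <- aperm(array(Y, dim = c(ns, ntr, nch)), c(2, 3, 1))
    fb <- ifelse(outcomes == "timeout", 6, round(runif(ntr, 2, 6), 2))
    meta <- data.frame(subject = subject, group = group, session = session,
                       condition = "down", outcome = outcomes,
                       feedback_duration = pmax(fb, cfg$epoch_length),
                       stringsAsFactors = FALSE)
    epoched_eeg(arr, fs, head$montage, meta)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Generates the head model (unless supplied), subject latents, behaviour
#' table, and per-subject two-session epoched EEG with the configured power
#' interaction, envelope-coupling change, artifacts, and
#' neural-behavioural correlations, together with a ground-truth record.
#'
#' @param config a `sim_config`.
#' @param head optional precomputed `list(montage, leadfield, parcellation)`
#'   to reuse across replicate cohorts.
#' @param eeg generate EEG (`TRUE`) or only structure + behaviour.
#' @return object of class `bci_cohort`: `subjects` (list of
#'   `list(id, group, sessions = list(first, last))`), `behavior`,
#'   `ground_truth`, `montage`, `leadfield`, `parcellation`, `config`.
#' @export
simulate_cohort <- function(config, head = NULL, eeg = TRUE) {
  cfg <- config
  if (is.null(head)) {
    montage <- make_montage(cfg$n_channels)
    hm <- with_seed(derive_seed(cfg$seed, "head"),
                    make_leadfield(montage, cfg$n_grid,
                                   seed = derive_seed(cfg$seed, "grid")))
    head <- list(montage = montage, leadfield = hm$leadfield,
                 parcellation = hm$parcellation)
  }
  targets <- define_targets(cfg, head$leadfield, head$parcellation)
  # power_effect_size is the standardized change difference the designated
  # sensors should carry; compensate the leadfield dilution (target share)
  beh <- simulate_behavior(cfg, boost = 1 / max(targets$target_share, 0.5))
  lat <- beh$latents
  baseline <- with_seed(derive_seed(cfg$seed, "baseline"),
                        cfg$sigma_b * rnorm(nrow(lat)))
  subjects <- vector("list", nrow(lat))
  for (i in seq_len(nrow(lat))) {
    sess <- list()
    if (eeg) {
      for (s in c("first", "last")) {
        counts <- beh$behavior[beh$behavior$subject == lat$subject[i] &
                                 beh$behavior$session == s, ]
        outc <- with_seed(derive_seed(cfg$seed, paste0("outc", i, s)),
                          sample(rep(c("hit", "miss", "timeout"),
                                     c(counts$hits, counts$misses,
                                       counts$timeouts))))
        sess[[s]] <- simulate_session_eeg(
          cfg, head, targets, lat$subject[i], lat$group[i], s,
          log_power_delta = lat$alpha_change[i],
          baseline_logamp = baseline[i], outcomes = outc,
          seed = derive_seed(cfg$seed, paste0("eeg", i, s)))
      }
    }
    subjects[[i]] <- list(id = lat$subject[i], group = lat$group[i],
                          sessions = sess)
  }
  gt <- list(target_grid_points = targets$target_grid_points,
             target_sensor_freq_elements = targets$target_sensor_freq_elements,
             target_channels = targets$target_channels,
             target_edges = targets$target_edges,
             coupled_rois = targets$coupled_rois,
             subject_alpha_change = setNames(lat$alpha_change, lat$subject))
  structure(list(subjects = subjects, behavior = beh$behavior,
                 ground_truth = gt, montage = head$montage,
                 leadfield = head$leadfield,
                 parcellation = head$parcellation, config = cfg),
            class = "bci_cohort")
}

#' Simulate a cohort of connectivity matrices
#'
#' The connectivity-level analogue of the EEG generator, for statistics on
#' the 90 x 90 envelope-correlation matrices at scale: per subject and
#' session, edge correlations are baseline values plus subject and session
#' noise on the Fisher-z scale; the target edges shift by
#' `-/+ delta_r` across sessions in the MBSR/control group. `delta_r`
#' defaults to `0.4 * coupling_delta`, the measured envelope-correlation
#' change the mixing-weight shift `w0 +/- coupling_delta/2` produces
#' (Delta r ~ attenuation x 2 w0 delta, attenuation ~ 0.5).
#'
#' @param config a `sim_config` (uses subject counts, coupling_delta, seed).
#' @param target_edges m x 2 ROI index pairs; defaults to the generator's
#'   fixed 10-edge subgraph on a 90-ROI parcellation.
#' @param n_roi number of ROIs (default 90).
#' @param delta_r session change of target-edge correlation per group.
#' @return list `conn` (subjects x 2 sessions list of matrices), `meta`
#'   (subject, group, session per entry), `diff` (subjects x roi x roi
#'   array of last - first), `group`, `target_edges`.
#' @export
simulate_connectivity_cohort <- function(config, target_edges = NULL,
                                         n_roi = 90,
                                         delta_r = 0.4 * config$coupling_delta) {
  cfg <- config
  n <- 2 * cfg$n_subjects_per_group
  group <- rep(c("MBSR", "control"), each = cfg$n_subjects_per_group)
  if (is.null(target_edges)) {
    mem <- seq_len(8) * 3                      # spread over the parcellation
    le <- rbind(cbind(1:7, 2:8), c(1, 4), c(3, 6), c(5, 8))
    target_edges <- cbind(mem[le[, 1]], mem[le[, 2]])
  }
  ut <- which(upper.tri(matrix(0, n_roi, n_roi)))
  npair <- length(ut)
  tgt_flat <- (target_edges[, 2] - 1) * n_roi + target_edges[, 1]
  tgt_idx <- match(tgt_flat, ut)
  with_seed(derive_seed(cfg$seed, "conncohort"), {
    mu <- 0.05 + abs(rnorm(npair, 0, 0.08))    # baseline z ~ resting envelope r
    conn <- list(); meta <- list()
    diff_arr <- array(0, dim = c(n, n_roi, n_roi))
    for (i in seq_len(n)) {
      subj_dev <- rnorm(npair, 0, 0.05)
      for (s in c("first", "last")) {
        zz <- mu + subj_dev + rnorm(npair, 0, 0.08)
        shift <- if (group[i] == "MBSR") c(first = delta_r / 2, last = -delta_r / 2)
        else c(first = -delta_r / 2, last = delta_r / 2)
        zz[tgt_idx] <- zz[tgt_idx] + shift[s]
        m <- matrix(0, n_roi, n_roi)
        m[ut] <- tanh(zz)
        m <- m + t(m)
        conn[[length(conn) + 1]] <- m
        meta[[length(meta) + 1]] <- data.frame(
          subject = sprintf("S%02d", i), group = group[i], session = s,
          stringsAsFactors = FALSE)
      }
      diff_arr[i, , ] <- conn[[length(conn)]] - conn[[length(conn) - 1]]
    }
    list(conn = conn, meta = do.call(rbind, meta), diff = diff_arr,
         group = group, target_edges = target_edges)
  })
}

#' Generate a pair of coupled analytic band signals
#'
#' Two narrowband analytic signals whose log-normal envelopes share a
#' common component with mixing weight `weight`; the measured orthogonalized
#' envelope correlation increases monotonically with `weight^2`. Used by
#' the connectivity recovery checks.
#'
#' @param n samples. @param weight mixing weight in [0, 1).
#' @param band Hz interval. @param fs sampling rate.
#' @param env_sd log-envelope SD. @param env_cut envelope cutoff (Hz).
#' @return complex matrix with two rows.
#' @export
make_coupled_pair <- function(n, weight, band = c(9, 15), fs = 250,
                              env_sd = 0.8, env_cut = 3) {
  stopifnot(weight >= 0, weight < 1)
  slow <- function() {
    e <- fft(fft(rnorm(n)) *
               (c(seq(0, fs, length.out = n + 1)[1:n] < env_cut |
                    seq(0, fs, length.out = n + 1)[1:n] > fs - env_cut)),
             inverse = TRUE)
    e <- Re(e); e / sd(e)
  }
  zc <- slow(); z1 <- slow(); z2 <- slow()
  e1 <- exp(env_sd * (weight * zc + sqrt(1 - weight^2) * z1))
  e2 <- exp(env_sd * (weight * zc + sqrt(1 - weight^2) * z2))
  c1 <- analytic_signal(narrowband_noise(n, band[1], band[2], fs))
  c2 <- analytic_signal(narrowband_noise(n, band[1], band[2], fs))
  rbind(c1 * e1, c2 * e2)
}

#' Write a cohort to disk as plain text
#'
#' One directory per subject with per-session epoch directories, plus
#' `behavior.csv`, `ground_truth.json`, `montage.tsv`, `parcellation.tsv`.
#'
#' @param cohort a `bci_cohort`. @param dir output directory.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$behavior, file.path(dir, "behavior.csv"), row.names = FALSE)
  gt <- cohort$ground_truth
  gt$target_edges <- unname(apply(gt$target_edges, 1, function(r) r,
                                  simplify = FALSE))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_montage_tsv(cohort$montage, file.path(dir, "montage.tsv"))
  write_parcellation_tsv(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  for (sub in cohort$subjects) {
    for (s in names(sub$sessions))
      write_epochs(sub$sessions[[s]], file.path(dir, sub$id, s))
  }
  invisible(dir)
}
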
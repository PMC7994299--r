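# End-to-end orchestration: simulate -> preprocess -> spectra -> source ->
# connectivity -> statistics -> summaries -> report.

#' Pipeline configuration
#'
#' All stage parameters with their study defaults (1-100 Hz filter, 250 Hz,
#' 1-50 Hz spectra, 9-15 Hz band, element threshold 0.05, NBS edge
#' threshold 0.005, 5000 permutations, 2 ICA components removed). Unknown
#' keys are rejected. The master seed fans out to per-stage substreams.
#'
#' @param ... overrides of the defaults listed below.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sim = sim_config(),
    filter_low = 1, filter_high = 100, target_rate = 250,
    window_length = 1, n_pca = 30, variance_z_threshold = 3.5,
    band = c(9, 15), lambda = 0.05,
    element_alpha = 0.05, edge_alpha = 0.005, n_perm = 5000,
    min_channels = 2, min_freqs = 2, min_size = 2,
    preprocess = TRUE, run_source = TRUE, run_connectivity = TRUE,
    power_log = TRUE, seed = 1, out_dir = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(defaults))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, ov)
  if (cfg$n_perm < 100) stop("n_perm must be >= 100")
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis on a synthetic cohort
#'
#' Generates (or accepts) a cohort, preprocesses every subject-session,
#' computes sensor spectra and the group x session interaction contrast,
#' runs the spatial-spectral sensor cluster permutation test, DICS source
#' maps with a spatial-only source cluster test, centroid envelope
#' connectivity with the network-based statistic, network summaries, the
#' PVC table, and the neural-behavioural correlations.
#'
#' @param config a `pipeline_config`.
#' @param cohort optional pre-built `bci_cohort` (simulated from
#'   `config$sim` when `NULL`).
#' @return object of class `pipeline_result` with a `manifest`.
#' @export
run_full_analysis <- function(config, cohort = NULL) {
  cfg <- config
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(cohort)) {
      sim <- cfg$sim
      sim$seed <- derive_seed(cfg$seed, "simulate")
      cohort <- simulate_cohort(sim)
    }
    nsub <- length(cohort$subjects)
    subjects <- vapply(cohort$subjects, `[[`, character(1), "id")
    groups <- vapply(cohort$subjects, `[[`, character(1), "group")
    if (setequal(unique(groups), c("MBSR", "control")))
      groups <- factor(groups, levels = c("MBSR", "control"))
    freqs <- 1:50
    nch <- length(cohort$montage$channel_names)

    stage <- "preprocess+spectra"
    sens_pow <- list(first = matrix(0, nsub, nch * length(freqs)),
                     last = matrix(0, nsub, nch * length(freqs)))
    clean <- vector("list", nsub)
    rejections <- list()
    for (i in seq_len(nsub)) {
      clean[[i]] <- list()
      for (s in c("first", "last")) {
        ep <- cohort$subjects[[i]]$sessions[[s]]
        if (cfg$preprocess) {
          ep <- preprocess(ep, low = cfg$filter_low, high = cfg$filter_high,
                           target_rate = cfg$target_rate,
                           n_pca = min(cfg$n_pca, nch),
                           window_length = cfg$window_length,
                           variance_z_threshold = cfg$variance_z_threshold,
                           seed = derive_seed(cfg$seed, paste0("ica", i, s)))
          rejections[[paste(subjects[i], s)]] <-
            attr(ep, "preprocess_report")$rejection$rejected
        }
        clean[[i]][[s]] <- ep
        sp <- compute_power_spectrum(ep, average = TRUE)
        sens_pow[[s]][i, ] <- as.vector(sp$power)
      }
    }

    stage <- "sensor_cluster_test"
    adj <- build_sensor_adjacency(cohort$montage, freqs)
    # interaction maps on log power by default: EEG power is log-normal
    # across subjects, and raw-scale differences let high-power subjects
    # dominate the group t statistics
    tf <- if (cfg$power_log) function(x) log10(x + 1e-12) else identity
    sens_diff <- tf(sens_pow$last) - tf(sens_pow$first)
    sensor_clusters <- cluster_permutation_test(
      sens_diff, groups, adj, element_alpha = cfg$element_alpha,
      n_perm = cfg$n_perm, min_channels = cfg$min_channels,
      min_freqs = cfg$min_freqs, seed = derive_seed(cfg$seed, "clusterperm"))

    source_clusters <- NULL; network_t <- NULL; source_t <- NULL
    if (cfg$run_source) {
      stage <- "source_localization"
      ng <- cfg$sim$n_grid
      src_pow <- list(first = matrix(0, nsub, ng),
                      last = matrix(0, nsub, ng))
      csd_pooled <- vector("list", nsub)
      for (i in seq_len(nsub)) {
        both <- abind_trials(clean[[i]]$first, clean[[i]]$last)
        csd_pooled[[i]] <- compute_csd(both, cfg$band)
        for (s in c("first", "last")) {
          csd_s <- compute_csd(clean[[i]][[s]], cfg$band)
          pm <- source_power_map(csd_s, cohort$leadfield, cfg$lambda)
          src_pow[[s]][i, ] <- pm$power
        }
      }
      gadj <- build_grid_adjacency(cohort$leadfield)
      source_clusters <- cluster_permutation_test(
        tf(src_pow$last) - tf(src_pow$first), groups, gadj,
        element_alpha = cfg$element_alpha, n_perm = cfg$n_perm,
        min_size = cfg$min_size,
        seed = derive_seed(cfg$seed, "sourceperm"))
      source_t <- source_clusters$element_t_map
      sig_mask <- unlist(lapply(
        Filter(function(cl) cl$significant, source_clusters$clusters),
        `[[`, "members"))
      network_t <- summed_t_by_network(source_t, sig_mask %||% integer(0),
                                       cohort$parcellation)
    }

    nbs <- NULL; degree_summary <- NULL; strength_summary <- NULL
    if (cfg$run_connectivity) {
      stage <- "connectivity+nbs"
      nroi <- length(cohort$parcellation$roi_names)
      diff_arr <- array(0, dim = c(nsub, nroi, nroi))
      conn_list <- list(); conn_meta <- list()
      for (i in seq_len(nsub)) {
        cms <- list()
        for (s in c("first", "last")) {
          tc <- roi_timecourses(clean[[i]][[s]], csd_pooled[[i]],
                                cohort$leadfield, cohort$parcellation,
                                cfg$band, cfg$lambda)
          cms[[s]] <- connectivity_matrix(tc)
          conn_list[[length(conn_list) + 1]] <- cms[[s]]
          conn_meta[[length(conn_meta) + 1]] <- data.frame(
            subject = subjects[i], group = groups[i], session = s)
        }
        # Fisher-z variance stabilization before differencing
        zc <- function(v) atanh(pmin(pmax(v, -0.999999), 0.999999))
        diff_arr[i, , ] <- zc(cms$last$values) - zc(cms$first$values)
      }
      nbs <- nbs_test(diff_arr, groups, edge_alpha = cfg$edge_alpha,
                      n_perm = cfg$n_perm,
                      seed = derive_seed(cfg$seed, "nbsperm"),
                      roi_names = cohort$parcellation$roi_names)
      if (length(nbs$components)) {
        top <- nbs$components[[1]]$edges
        degree_summary <- mean_degree_by_network(top, cohort$parcellation)
        strength_summary <- mean_strength_change(
          top, conn_list, do.call(rbind, conn_meta))
      }
    }

    stage <- "behavior"
    beh <- compute_pvc(cohort$behavior)
    pvc_wide <- stats::reshape(
      beh[, c("subject", "group", "session", "pvc", "minutes")],
      idvar = c("subject", "group"), timevar = "session", direction = "wide")
    dpvc <- pvc_wide$pvc.last - pvc_wide$pvc.first
    # neural change: mean sensor power change over the top cluster's
    # elements (falls back to the full effect band when nothing survives)
    sig_cl <- Filter(function(cl) cl$significant, sensor_clusters$clusters)
    mask <- if (length(sig_cl)) sig_cl[[1]]$members else
      which(adj$node_freq >= cfg$band[1] & adj$node_freq <= cfg$band[2])
    neural <- rowMeans(sens_diff[, mask, drop = FALSE])
    neural <- neural[match(pvc_wide$subject, subjects)]
    cor_minutes <- correlate_neural_behavior(neural, pvc_wide$minutes.first)
    cor_pvc <- correlate_neural_behavior(neural, dpvc)

    out <- structure(list(
      sensor_clusters = sensor_clusters, source_clusters = source_clusters,
      source_t = source_t, network_t = network_t, nbs = nbs,
      degree_summary = degree_summary, strength_summary = strength_summary,
      behavior = beh, pvc_wide = pvc_wide,
      cor_minutes = cor_minutes, cor_pvc = cor_pvc,
      adjacency = adj, ground_truth = cohort$ground_truth,
      config = cfg, rejections = rejections),
      class = "pipeline_result")
    out$manifest <- build_manifest(out)
    if (!is.null(cfg$out_dir)) save_results(out, cfg$out_dir)
    out
  }, error = function(e)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  res
}

# Concatenate the trials of two recordings sharing montage and rate.
abind_trials <- function(a, b) {
  stopifnot(a$sampling_rate == b$sampling_rate)
  d1 <- dim(a$data); d2 <- dim(b$data)
  arr <- array(0, dim = c(d1[1] + d2[1], d1[2], d1[3]))
  arr[seq_len(d1[1]), , ] <- a$data
  arr[d1[1] + seq_len(d2[1]), , ] <- b$data
  epoched_eeg(arr, a$sampling_rate, a$montage,
              rbind(a$trial_meta, b$trial_meta))
}

build_manifest <- function(res) {
  sig <- function(x) if (is.null(x)) NA_real_ else
    round(sum(abs(x), na.rm = TRUE), 6)
  list(created = format(Sys.time(), tz = "UTC"),
       seed = res$config$seed,
       n_perm = res$config$n_perm,
       stages = c("simulate", "preprocess", "spectra", "sensor_cluster_test",
                  if (!is.null(res$source_clusters)) "source_localization",
                  if (!is.null(res$nbs)) "connectivity+nbs",
                  "behavior", "report"),
       checksums = list(
         sensor_t = sig(res$sensor_clusters$element_t_map),
         source_t = sig(res$source_t),
         nbs_t = sig(res$nbs$edge_t_map),
         pvc = sig(res$behavior$pvc)),
       trial_rejections = lengths(res$rejections))
}

save_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    serialize_results(res), file.path(dir, "results.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(write_report(res), file.path(dir, "report.md"))
  cfg <- res$config
  cfg$sim <- unclass(cfg$sim)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

serialize_results <- function(res) {
  cl2l <- function(cl) list(members = cl$members, mass = cl$mass,
                            sign = cl$sign, p_value = cl$p_value,
                            significant = cl$significant)
  list(
    sensor_clusters = lapply(res$sensor_clusters$clusters, cl2l),
    source_clusters = lapply(res$source_clusters$clusters %||% list(), cl2l),
    nbs_components = lapply(res$nbs$components %||% list(), function(cp)
      list(edges = apply(cp$edges, 1, function(r) r, simplify = FALSE),
           size = cp$size, p_value = cp$p_value,
           significant = cp$significant)),
    network_t = as.list(res$network_t %||% list()),
    cor_minutes = res$cor_minutes, cor_pvc = res$cor_pvc,
    manifest = res$manifest)
}

#' Human-readable markdown report
#'
#' @param results a `pipeline_result`.
#' @return character vector of markdown lines.
#' @export
write_report <- function(results) {
  r <- results
  lines <- c("# Intentional-rest BCI alpha analysis report", "")
  fmt_cluster <- function(cl, adj) {
    ch <- unique(adj$node_channel[cl$members])
    fr <- range(adj$node_freq[cl$members])
    sprintf("| %d-%d Hz | %d | %.1f | %.4f | %s |",
            fr[1], fr[2], length(ch), cl$mass, cl$p_value,
            ifelse(cl$significant, "yes", "no"))
  }
  sig <- Filter(function(cl) cl$significant, r$sensor_clusters$clusters)
  lines <- c(lines, "## Sensor-level cluster permutation test", "")
  if (length(r$sensor_clusters$clusters) == 0) {
    lines <- c(lines, "no significant clusters", "")
  } else {
    lines <- c(lines,
               "| band extent | channels | mass (sum t) | p | significant |",
               "|---|---|---|---|---|",
               vapply(r$sensor_clusters$clusters, fmt_cluster, character(1),
                      adj = r$adjacency), "")
    if (!length(sig)) lines <- c(lines, "no significant clusters", "")
  }
  if (!is.null(r$network_t)) {
    lines <- c(lines, "## Summed significant source t by network", "",
               paste0("- ", names(r$network_t), ": ",
                      sprintf("%.1f", r$network_t)), "")
  }
  lines <- c(lines, "## Network-based statistic", "")
  if (is.null(r$nbs) || length(r$nbs$components) == 0) {
    lines <- c(lines, "no components (no suprathreshold edges)", "")
  } else {
    lines <- c(lines, "| regions | edges | p | significant |", "|---|---|---|---|",
               vapply(r$nbs$components, function(cp)
                 sprintf("| %d | %d | %.4f | %s |",
                         length(unique(as.vector(cp$edges))), cp$size,
                         cp$p_value, ifelse(cp$significant, "yes", "no")),
                 character(1)), "")
  }
  agg <- stats::aggregate(pvc ~ group + session, data = r$behavior, FUN = mean)
  lines <- c(lines, "## PVC by group and session", "",
             "| group | session | mean PVC |", "|---|---|---|",
             sprintf("| %s | %s | %.3f |", agg$group, agg$session, agg$pvc), "",
             "## Neural-behavioural correlations", "",
             sprintf("- alpha change vs practice minutes: r = %.3f, p = %.4f, n = %d",
                     r$cor_minutes$r, r$cor_minutes$p, r$cor_minutes$n),
             sprintf("- alpha change vs PVC change: r = %.3f, p = %.4f, n = %d",
                     r$cor_pvc$r, r$cor_pvc$p, r$cor_pvc$n))
  lines
}
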
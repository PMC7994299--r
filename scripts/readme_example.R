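suppressMessages(library(restalpha))
## simulate a two-session cohort (20 MBSR + 20 controls)
cfg <- sim_config(n_subjects_per_group = 20, n_trials_per_session = 30,
                  n_grid = 120, seed = 7)
cohort <- simulate_cohort(cfg)

## sensor spectra -> per-subject interaction maps (log10 power, last - first)
pow <- lapply(c(first = "first", last = "last"), function(s)
  t(sapply(cohort$subjects, function(su)
    as.vector(compute_power_spectrum(su$sessions[[s]], average = TRUE)$power))))
maps <- log10(pow$last) - log10(pow$first)
group <- factor(sapply(cohort$subjects, `[[`, "group"),
                levels = c("MBSR", "control"))

## spatial-spectral cluster permutation test
adj <- build_sensor_adjacency(cohort$montage, 1:50)
cl <- cluster_permutation_test(maps, group, adj, n_perm = 1000, seed = 7)
top <- cl$clusters[[1]]
cat(sprintf("top cluster: %d-%d Hz, %d channels, mass %.1f, p = %.4f\n",
            min(adj$node_freq[top$members]), max(adj$node_freq[top$members]),
            length(unique(adj$node_channel[top$members])), top$mass,
            top$p_value))

## NBS on connectivity difference matrices
cc <- simulate_connectivity_cohort(cfg)
nb <- nbs_test(cc$diff, factor(cc$group, levels = c("MBSR", "control")),
               n_perm = 1000, seed = 7)
t1 <- nb$components[[1]]
cat(sprintf("top NBS component: %d edges over %d regions, p = %.4f\n",
            t1$size, length(unique(as.vector(t1$edges))), t1$p_value))

## behaviour: PVC and neural-behavioural correlations
beh <- compute_pvc(cohort$behavior)
print(aggregate(pvc ~ group + session, beh, function(x) round(mean(x), 3)))
wide <- reshape(beh[, c("subject", "group", "session", "pvc", "minutes")],
                idvar = c("subject", "group"), timevar = "session",
                direction = "wide")
inj <- with(cohort$ground_truth$target_sensor_freq_elements,
            channel + (freq - 1) * 64)
alpha_change <- rowMeans(maps[, inj])[match(wide$subject,
                                            sapply(cohort$subjects, `[[`, "id"))]
cm <- correlate_neural_behavior(alpha_change, wide$minutes.first)
cp <- correlate_neural_behavior(alpha_change, wide$pvc.last - wide$pvc.first)
cat(sprintf("alpha change vs practice minutes: r = %.2f, p = %.3f\n", cm$r, cm$p))
cat(sprintf("alpha change vs PVC change:       r = %.2f, p = %.3f\n", cp$r, cp$p))
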
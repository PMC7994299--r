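# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# memoised constructors: montages, head models, adjacency graphs
fx <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

fx_montage64 <- function() fx("m64", function() make_montage(64))
fx_montage32 <- function() fx("m32", function() make_montage(32))

fx_head32 <- function() fx("head32", function() {
  m <- make_montage(32)
  h <- make_leadfield(m, 150, seed = 7)
  list(montage = m, leadfield = h$leadfield, parcellation = h$parcellation)
})

fx_head64 <- function() fx("head64", function() {
  m <- make_montage(64)
  h <- make_leadfield(m, 120, seed = 101)
  list(montage = m, leadfield = h$leadfield, parcellation = h$parcellation)
})

fx_adj32 <- function() fx("adj32", function()
  build_sensor_adjacency(fx_head32()$montage, 1:50))

fx_adj64 <- function() fx("adj64", function()
  build_sensor_adjacency(fx_head64()$montage, 1:50))

# a small epoched recording of white noise
noise_epochs <- function(montage, n_trials = 4, n_samples = 500, fs = 250,
                         sd = 1, seed = 1) {
  set.seed(seed)
  nch <- length(montage$channel_names)
  epoched_eeg(array(rnorm(n_trials * nch * n_samples, 0, sd),
                    c(n_trials, nch, n_samples)), fs, montage)
}

# put a single-channel signal into an otherwise silent recording
signal_epochs <- function(montage, channel, signal, fs = 250, n_trials = 1) {
  nch <- length(montage$channel_names)
  ns <- length(signal)
  arr <- array(0, c(n_trials, nch, ns))
  arr[, match(channel, montage$channel_names), ] <-
    matrix(signal, n_trials, ns, byrow = TRUE)
  epoched_eeg(arr, fs, montage)
}

rms <- function(x) sqrt(mean(x^2))

# measured sensor interaction maps (log10 band power change) for a cohort
cohort_interaction_maps <- function(cohort) {
  pow <- lapply(c(first = "first", last = "last"), function(s)
    t(vapply(cohort$subjects, function(su)
      as.vector(compute_power_spectrum(su$sessions[[s]], average = TRUE)$power),
      numeric(length(cohort$montage$channel_names) * 50))))
  list(values = log10(pow$last + 1e-12) - log10(pow$first + 1e-12),
       group = factor(vapply(cohort$subjects, `[[`, character(1), "group"),
                      levels = c("MBSR", "control")))
}
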
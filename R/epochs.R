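#' Epoched EEG container
#'
#' The common currency of the pipeline: a `trials x channels x samples`
#' numeric array (microvolts) with its sampling rate, montage, and per-trial
#' metadata (`subject`, `group`, `session`, `condition`, `outcome`,
#' `feedback_duration` in seconds).
#'
#' @param data trials x channels x samples array.
#' @param sampling_rate sampling rate in Hz.
#' @param montage a `sensor_montage` with as many channels as `dim(data)[2]`.
#' @param trial_meta data.frame with one row per trial.
#' @return object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, sampling_rate, montage, trial_meta = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (dim(data)[2] != length(montage$channel_names))
    stop("channel dimension does not match montage")
  if (is.null(trial_meta))
    trial_meta <- data.frame(trial = seq_len(dim(data)[1]))
  if (nrow(trial_meta) != dim(data)[1])
    stop("trial_meta rows must match number of trials")
  if ("feedback_duration" %in% names(trial_meta) &&
      any(trial_meta$feedback_duration <= 0 | trial_meta$feedback_duration > 6))
    stop("feedback_duration must lie in (0, 6] seconds")
  structure(list(data = data, sampling_rate = sampling_rate,
                 montage = montage, trial_meta = trial_meta),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %d trials x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$sampling_rate))
  invisible(x)
}

#' @export
dim.epoched_eeg <- function(x) dim(x$data)

n_trials <- function(x) dim(x$data)[1]
n_channels <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

# Replace the data array, keeping metadata consistent.
set_data <- function(x, data, sampling_rate = x$sampling_rate,
                     trial_meta = x$trial_meta) {
  x$data <- data
  x$sampling_rate <- sampling_rate
  x$trial_meta <- trial_meta
  x
}

#' Write / read epoched EEG as plain text
#'
#' One directory per recording: `data.csv` holds the array flattened to
#' `(trial, channel)` rows by `sample` columns; `meta.json` holds the
#' sampling rate and per-trial metadata; `montage.tsv` the sensor table.
#'
#' @param x an `epoched_eeg`.
#' @param dir output directory (created if missing).
#' @export
write_epochs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(x$data)
  flat <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[1] * d[2], byrow = TRUE)
  utils::write.table(format(flat, digits = 8, trim = TRUE),
                     file.path(dir, "data.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(sampling_rate = x$sampling_rate, dims = d,
               trial_meta = x$trial_meta)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  write_montage_tsv(x$montage, file.path(dir, "montage.tsv"))
  invisible(dir)
}

#' @rdname write_epochs
#' @param dir directory written by `write_epochs`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  flat <- as.matrix(utils::read.table(file.path(dir, "data.csv"), sep = ","))
  arr <- aperm(array(t(flat), dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  montage <- read_montage_tsv(file.path(dir, "montage.tsv"))
  epoched_eeg(arr, meta$sampling_rate, montage,
              as.data.frame(meta$trial_meta))
}
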
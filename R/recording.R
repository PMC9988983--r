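#' Multi-channel PSG recording
#'
#' Container for a polysomnography recording: a channel-by-sample signal
#' matrix over referential electrodes, the sampling rate, the scored
#' hypnogram and subject/dataset/center/age metadata. Signals are stored per
#' referential electrode; channel derivations (e.g. C4-M1) are computed
#' downstream by the montage functions.
#'
#' @param signals numeric matrix, one row per electrode.
#' @param fs sampling rate in Hz.
#' @param electrodes character vector of unique electrode labels, one per
#'   signal row.
#' @param hypnogram a [stage_sequence()].
#' @param subject_id,family_id,dataset_id,recording_id,center_id identifiers.
#' @param age subject age in years, or `NULL`.
#' @param center_params list describing acquisition-center effects
#'   (`gain`, `lowpass` Hz or `NULL`, `scorer_confusion` matrix or `NULL`).
#' @param latent_hypnogram the uncorrupted stage sequence when scorer noise
#'   was applied (diagnostics only), or `NULL`.
#' @param hypnogram_start_epoch number of whole epochs of signal preceding
#'   the first scored epoch (consumed by [trim_to_hypnogram()]).
#' @return an object of class `psg_recording`.
#' @export
psg_recording <- function(signals, fs, electrodes, hypnogram,
                          subject_id = "S1", family_id = subject_id,
                          dataset_id = "D1", recording_id = NULL,
                          center_id = dataset_id, age = NULL,
                          center_params = NULL, latent_hypnogram = NULL,
                          hypnogram_start_epoch = 0L) {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1)
  if (fs <= 0) stop("fs must be positive")
  electrodes <- as.character(electrodes)
  if (nrow(signals) != length(electrodes))
    stop("one electrode label per signal row required")
  if (anyDuplicated(electrodes)) stop("electrode labels must be unique")
  if (!inherits(hypnogram, "stage_sequence"))
    hypnogram <- stage_sequence(hypnogram)
  need <- 30 * fs * (hypnogram_start_epoch + length(hypnogram))
  if (ncol(signals) < need)
    stop(sprintf("signal too short: %d samples < %d required by hypnogram",
                 ncol(signals), need))
  rownames(signals) <- electrodes
  structure(list(signals = signals, fs = fs, electrodes = electrodes,
                 hypnogram = hypnogram, subject_id = subject_id,
                 family_id = family_id, dataset_id = dataset_id,
                 recording_id = recording_id %||%
                   paste0(dataset_id, "_", subject_id, "_r1"),
                 center_id = center_id, age = age,
                 center_params = center_params,
                 latent_hypnogram = latent_hypnogram,
                 hypnogram_start_epoch = as.integer(hypnogram_start_epoch)),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat("<psg_recording> ", x$recording_id, ": ",
      nrow(x$signals), " electrodes x ", ncol(x$signals), " samples @ ",
      x$fs, " Hz, ", length(x$hypnogram), " scored epochs\n", sep = "")
  cat("  electrodes:", paste(x$electrodes, collapse = " "), "\n")
  if (!is.null(x$age)) cat("  age:", x$age, "years\n")
  invisible(x)
}

n_epochs <- function(recording) length(recording$hypnogram)

epoch_samples_of <- function(recording) as.integer(30 * recording$fs)

# Extract the signal rows for epochs [from, from + n - 1] (1-based epochs).
epoch_slice <- function(recording, from, n) {
  i <- epoch_samples_of(recording)
  a <- (from - 1L) * i + 1L
  recording$signals[, a:(a + n * i - 1L), drop = FALSE]
}

#' Collection of PSG recordings
#'
#' @param recordings list of [psg_recording()] objects.
#' @return list of class `psg_cohort`.
#' @export
psg_cohort <- function(recordings) {
  if (!length(recordings)) stop("empty cohort")
  if (!all(vapply(recordings, inherits, TRUE, "psg_recording")))
    stop("all elements must be psg_recording objects")
  structure(recordings, class = "psg_cohort")
}

#' @export
print.psg_cohort <- function(x, ...) {
  ds <- vapply(x, `[[`, "", "dataset_id")
  cat("<psg_cohort> ", length(x), " recordings in ",
      length(unique(ds)), " dataset(s)\n", sep = "")
  print(table(ds))
  invisible(x)
}

#' @export
`[.psg_cohort` <- function(x, i) psg_cohort(unclass(x)[i])

#' Dataset identifiers of a cohort's recordings
#' @param cohort a [psg_cohort()] or list of recordings.
#' @return character vector, one dataset id per recording.
#' @export
cohort_dataset_ids <- function(cohort) vapply(cohort, `[[`, "", "dataset_id")
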
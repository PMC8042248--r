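#' Multichannel scalp EEG recording
#'
#' Lightweight container for a multichannel EEG recording in microvolts.
#' `samples` is a channels-by-time numeric matrix, `labels` names its rows.
#' `space` distinguishes raw electrode recordings ("electrode", e.g. read
#' from EDF) from bipolar-derived recordings ("bipolar", e.g. produced by
#' [make_bipolar_montage()] or the simulator, whose channel labels are
#' derivation names such as "P3-O1").
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs_hz sampling rate in Hz (> 0).
#' @param labels character vector of channel labels, one per row, unique.
#' @param annotations data.frame with columns `onset_s`, `duration_s`,
#'   `label`; used for sleep stages (e.g. "W", "N1".."N3", "REM") and
#'   artifact spans (label "artifact" or "bad").
#' @param meta named list of patient metadata (see [patient_meta()]).
#' @param space "electrode" or "bipolar".
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs_hz, labels,
                          annotations = empty_annotations(),
                          meta = list(), space = c("electrode", "bipolar")) {
  space <- match.arg(space)
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop("fs_hz must be a single positive number")
  if (length(labels) != nrow(samples))
    stop("length(labels) must equal nrow(samples)")
  if (anyDuplicated(labels))
    stop("channel labels must be unique")
  annotations <- as.data.frame(annotations)
  needed <- c("onset_s", "duration_s", "label")
  if (!all(needed %in% names(annotations)))
    stop("annotations must have columns onset_s, duration_s, label")
  dur <- ncol(samples) / fs_hz
  if (nrow(annotations) &&
      any(annotations$onset_s < 0 |
          annotations$onset_s + annotations$duration_s > dur + 1e-9))
    stop("annotation spans must lie within the record")
  rownames(samples) <- labels
  structure(list(samples = samples, fs_hz = fs_hz, labels = labels,
                 annotations = annotations, meta = meta, space = space),
            class = "eeg_recording")
}

empty_annotations <- function() {
  data.frame(onset_s = numeric(0), duration_s = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %s space\n",
              nrow(x$samples), ncol(x$samples), x$fs_hz,
              ncol(x$samples) / x$fs_hz, x$space))
  cat("  channels:", paste(utils::head(x$labels, 8), collapse = ", "),
      if (length(x$labels) > 8) "..." else "", "\n")
  if (nrow(x$annotations))
    cat("  annotations:", nrow(x$annotations), "spans (",
        paste(unique(x$annotations$label), collapse = ", "), ")\n")
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return seconds.
#' @export
recording_duration <- function(rec) ncol(rec$samples) / rec$fs_hz

#' Patient metadata
#'
#' @param age_years age in decimal years (> 0).
#' @param sex "F" or "M".
#' @param classification "focal" or "generalized".
#' @param aetiology "structural", "genetic" or "unknown".
#' @param csws logical; continuous spike-and-wave during sleep (consumed as
#'   a metadata flag, never computed from EEG here).
#' @param seizures_per_month positive number of seizures per month.
#' @param patient_id identifier.
#' @return named list.
#' @export
patient_meta <- function(age_years, sex = NA_character_,
                         classification = c("focal", "generalized"),
                         aetiology = c("structural", "genetic", "unknown"),
                         csws = FALSE, seizures_per_month = NA_real_,
                         patient_id = NA) {
  if (!is.na(age_years) && age_years <= 0) stop("age_years must be positive")
  if (!is.na(seizures_per_month) && seizures_per_month <= 0)
    stop("seizures_per_month must be positive")
  list(patient_id = patient_id, age_years = age_years, sex = sex,
       classification = match.arg(classification),
       aetiology = match.arg(aetiology), csws = isTRUE(csws),
       seizures_per_month = seizures_per_month)
}
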
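#' Per-channel HFO rates
#'
#' Rate = number of accepted events on the channel divided by the total
#' analyzed minutes (5 min times the number of intervals).
#'
#' @param events `hfo_events` data.frame; only `status == "accepted"` rows
#'   count (a plain data.frame without `status` counts every row).
#' @param intervals data.frame from [select_intervals()], or `NULL` if
#'   `minutes` is given.
#' @param channels channels to report (zero rates included); defaults to
#'   the channels present in `events`.
#' @param minutes total analyzed minutes, overrides `intervals`.
#' @return data.frame `channel`, `event_count`, `total_minutes`, `rate`
#'   (HFO/min), sorted by decreasing rate.
#' @export
channel_rates <- function(events, intervals = NULL, channels = NULL,
                          minutes = NULL) {
  if (is.null(minutes)) {
    if (is.null(intervals)) stop("provide intervals or minutes")
    minutes <- total_minutes(intervals)
  }
  if (minutes <= 0) stop("division error: zero analyzed time")
  acc <- if ("status" %in% names(events))
    events[events$status == "accepted", , drop = FALSE] else events
  if (is.null(channels)) channels <- sort(unique(acc$channel))
  cnt <- table(factor(acc$channel, levels = channels))
  out <- data.frame(channel = channels, event_count = as.integer(cnt),
                    total_minutes = minutes,
                    rate = as.integer(cnt) / minutes,
                    stringsAsFactors = FALSE)
  out[order(-out$rate, -out$event_count, out$channel), , drop = FALSE]
}

#' Event frequency from crest intervals
#'
#' Frequency of the crest and trough waves: the reciprocal of the mean
#' consecutive crest-to-crest interval of the band-passed trace, where
#' crests are local maxima above zero. The result is clipped to the ripple
#' band.
#'
#' @param seg band-passed event segment.
#' @param fs sampling rate in Hz.
#' @param band clipping band, default `c(80, 250)`.
#' @param method "crest" (default) or "fft" (spectral-peak alternative for
#'   sensitivity analysis).
#' @return frequency in Hz.
#' @export
event_frequency <- function(seg, fs, band = c(80, 250),
                            method = c("crest", "fft")) {
  method <- match.arg(method)
  if (method == "fft") {
    n <- length(seg)
    spec <- Mod(stats::fft(seg))[1:(floor(n / 2) + 1)]
    f <- (0:floor(n / 2)) * fs / n
    inb <- f >= band[1] & f <= band[2]
    return(f[inb][which.max(spec[inb])])
  }
  n <- length(seg)
  if (n < 3) stop("undefined-frequency error: segment too short")
  crest <- which(seg[2:(n - 1)] > seg[1:(n - 2)] &
                   seg[2:(n - 1)] >= seg[3:n] &
                   seg[2:(n - 1)] > 0) + 1
  if (length(crest) < 2)
    stop("undefined-frequency error: fewer than 2 crests")
  f <- 1 / mean(diff(crest) / fs)
  min(max(f, band[1]), band[2])
}

#' Event duration from the threshold-exceeding envelope run
#'
#' Duration is the time the Hilbert envelope of the event remains above the
#' detection threshold, i.e. the length of the run that defines the event.
#' @param onset_sample,offset_sample half-open run in samples.
#' @param fs sampling rate in Hz.
#' @return duration in ms.
#' @export
event_duration <- function(onset_sample, offset_sample, fs) {
  (offset_sample - onset_sample) / fs * 1000
}

#' Event amplitude: highest peak-to-peak swing
#'
#' Maximum absolute difference between adjacent extrema (crest/trough
#' pairs) of the band-passed segment.
#' @param seg band-passed event segment.
#' @return amplitude in microvolts.
#' @export
event_amplitude <- function(seg) {
  n <- length(seg)
  if (n < 3) return(max(seg) - min(seg))
  d <- diff(seg)
  ext <- which(d[-1] * d[-length(d)] < 0) + 1
  ext <- c(1, ext, n)
  if (length(ext) < 2) return(max(seg) - min(seg))
  max(abs(diff(seg[ext])))
}

#' Event signal-to-noise ratio against 0.5-s flanks
#'
#' SNR = mean power of the band-passed trace within the event divided by
#' the mean power over the 0.5-s stretches before and after it
#' (concatenated). Near interval edges the available flank portion is used
#' if it is at least `min_flank_s` per side; otherwise the SNR is `NA`
#' (the detector drops such events with a distinct status). Zero flank
#' power on a non-silent event yields `Inf` with a warning.
#'
#' @param xb band-passed channel trace.
#' @param onset_sample,offset_sample half-open event span in samples.
#' @param fs sampling rate in Hz.
#' @param flank_s nominal flank duration per side (default 0.5 s).
#' @param min_flank_s minimum usable flank per side (default 0.25 s).
#' @return power ratio.
#' @export
event_snr <- function(xb, onset_sample, offset_sample, fs,
                      flank_s = 0.5, min_flank_s = 0.25) {
  nf <- round(flank_s * fs)
  pre <- xb[max(1, onset_sample - nf):(onset_sample - 1)]
  post_end <- min(length(xb), offset_sample - 1 + nf)
  post <- if (offset_sample <= length(xb)) xb[offset_sample:post_end] else numeric(0)
  if (length(pre) < min_flank_s * fs || length(post) < min_flank_s * fs)
    return(NA_real_)
  ev <- xb[onset_sample:(offset_sample - 1)]
  pf <- mean(c(pre, post)^2)
  pe <- mean(ev^2)
  if (pf == 0) {
    if (pe == 0) return(NA_real_)
    warning("zero flank power: returning infinite SNR")
    return(Inf)
  }
  pe / pf
}

#' Ripple-band activity (RBA)
#'
#' Mean over the analysis intervals of the per-interval root-mean-square of
#' the 80-250 Hz band-passed signal on one channel (by convention the
#' channel with the highest HFO rate). A background-noise measure in
#' microvolts.
#'
#' @param x raw signal of the chosen channel (full record).
#' @param intervals data.frame from [select_intervals()].
#' @param fs sampling rate in Hz.
#' @param band ripple band, default `c(80, 250)`.
#' @return RBA in microvolts.
#' @export
ripple_band_activity <- function(x, intervals, fs, band = c(80, 250)) {
  rms <- vapply(seq_len(nrow(intervals)), function(k) {
    i0 <- round(intervals$start_s[k] * fs) + 1
    i1 <- round(intervals$end_s[k] * fs)
    sqrt(mean(bandpass_ripple(x[i0:i1], fs, band)^2))
  }, 0)
  mean(rms)
}

#' Patient-level HFO summary
#'
#' Determines the channel with the highest HFO rate (ties broken by higher
#' event count, then lexicographic channel name), computes the means of
#' event frequency, duration, amplitude and SNR over the accepted events on
#' that channel, and the RBA there. Morphology means are reported only when
#' the patient has more than 3 accepted HFOs (`morphology_valid`).
#'
#' @param events `hfo_events` from [detect_hfo()].
#' @param intervals analysis intervals used for detection.
#' @param rec the recording (bipolar space) used for detection; needed for
#'   the RBA. May be `NULL`, in which case `rba_uv` is `NA`.
#' @param channels optional full channel list for the rate profile.
#' @return one-row data.frame (`patient_id`, `age_years`, `n_intervals`,
#'   `n_events`, `rate_top`, `top_channel`, `mean_frequency_hz`,
#'   `mean_duration_ms`, `mean_amplitude_uv`, `mean_snr`, `rba_uv`,
#'   `morphology_valid`).
#' @export
summarize_patient <- function(events, intervals, rec = NULL,
                              channels = NULL) {
  if (is.null(channels) && !is.null(rec)) channels <- rec$labels
  acc <- events[events$status == "accepted", , drop = FALSE]
  prof <- channel_rates(events, intervals, channels = channels)
  meta <- if (!is.null(rec)) rec$meta else list()
  n_events <- nrow(acc)
  if (n_events == 0 || !nrow(prof) || max(prof$rate) == 0) {
    top <- NA_character_; rate_top <- 0
  } else {
    top <- prof$channel[1]
    rate_top <- prof$rate[1]
  }
  morph <- n_events > 3
  on_top <- acc[!is.na(top) & acc$channel == top, , drop = FALSE]
  mstat <- function(v) if (morph && nrow(on_top)) mean(v) else NA_real_
  rba <- if (!is.null(rec) && !is.na(top))
    ripple_band_activity(rec$samples[top, ], intervals, rec$fs_hz) else NA_real_
  data.frame(
    patient_id = if (!is.null(meta$patient_id)) meta$patient_id else NA,
    age_years = if (!is.null(meta$age_years)) meta$age_years else NA_real_,
    n_intervals = nrow(intervals), n_events = n_events,
    rate_top = rate_top, top_channel = top,
    mean_frequency_hz = mstat(on_top$frequency_hz),
    mean_duration_ms = mstat(on_top$duration_ms),
    mean_amplitude_uv = mstat(on_top$amplitude_uv),
    mean_snr = mstat(on_top$snr),
    rba_uv = rba, morphology_valid = morph,
    stringsAsFactors = FALSE)
}
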
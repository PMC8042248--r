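#' Detector configuration
#'
#' The ripple band and the Stage III constants (40 uV amplitude ceiling,
#' SNR floor of 4, bilateral partial-overlap rejection) are the published
#' part of the detector and default to those values. The Stage I/II numeric
#' constants are free parameters of this implementation, documented here:
#'
#' * `entropy_window_s` (1 s): window for the Stockwell-entropy baseline
#'   scan.
#' * `baseline_entropy_quantile` (0.75): windows whose in-band entropy is at
#'   or above this quantile count as baseline (least oscillatory quarter).
#' * `threshold_multiplier` (1.0): detection threshold = multiplier x the
#'   median over baseline windows of the per-window envelope maximum; the
#'   per-window maximum of near-Rayleigh noise is a stable high quantile of
#'   the envelope, so the median across windows is robust to residual
#'   oscillatory contamination.
#' * `min_duration_ms` (20): minimum above-threshold run, about 4 cycles at
#'   200 Hz / 2 cycles at 100 Hz.
#' * `min_oscillations` (4): minimum number of rectified-signal peaks above
#'   half the threshold inside the run.
#' * `merge_gap_ms` (10): runs closer than this merge into one event.
#' * `stage2_trough_ratio` (0.5): Stage II keeps an event iff the spectral
#'   trough between the low-frequency (<40 Hz) power maximum and the ripple
#'   peak is at most this fraction of the ripple peak power (boundary
#'   inclusive).
#'
#' @param band_hz ripple band, default `c(80, 250)`.
#' @param entropy_window_s,baseline_entropy_quantile,threshold_multiplier
#'   Stage I baseline parameters (see Details).
#' @param min_duration_ms,min_oscillations,merge_gap_ms event run filters.
#' @param stage2_trough_ratio Stage II isolation criterion.
#' @param amplitude_reject_uv Stage III amplitude ceiling (reject >= this).
#' @param snr_reject Stage III SNR floor (reject < this).
#' @param flank_s,min_flank_s SNR flank duration and the minimum usable
#'   flank near interval edges (events with less are dropped with status
#'   `rejected_edge`).
#' @param freq_step_hz frequency sampling of the entropy scan.
#' @return named list of class `detector_config`.
#' @export
detector_config <- function(band_hz = c(80, 250),
                            entropy_window_s = 1,
                            baseline_entropy_quantile = 0.75,
                            threshold_multiplier = 1.0,
                            min_duration_ms = 20,
                            min_oscillations = 4,
                            merge_gap_ms = 10,
                            stage2_trough_ratio = 0.5,
                            amplitude_reject_uv = 40,
                            snr_reject = 4,
                            flank_s = 0.5,
                            min_flank_s = 0.25,
                            freq_step_hz = 5) {
  cfg <- list(band_hz = band_hz, entropy_window_s = entropy_window_s,
              baseline_entropy_quantile = baseline_entropy_quantile,
              threshold_multiplier = threshold_multiplier,
              min_duration_ms = min_duration_ms,
              min_oscillations = min_oscillations,
              merge_gap_ms = merge_gap_ms,
              stage2_trough_ratio = stage2_trough_ratio,
              amplitude_reject_uv = amplitude_reject_uv,
              snr_reject = snr_reject, flank_s = flank_s,
              min_flank_s = min_flank_s, freq_step_hz = freq_step_hz,
              stage_order = "I-II-III")
  if (band_hz[1] <= 0 || band_hz[2] <= band_hz[1])
    stop("invalid band")
  class(cfg) <- "detector_config"
  cfg
}

runs_above <- function(above) {
  # maximal runs of TRUE; returns matrix [onset, offset) 1-based/0-based mix:
  # onset = first index, offset = last index + 1
  d <- diff(c(FALSE, above, FALSE))
  cbind(onset = which(d == 1), offset = which(d == -1))
}

#' Stage I: baseline-relative envelope thresholding
#'
#' Determines a baseline amplitude threshold in time windows with high
#' Stockwell entropy (low oscillatory activity) in the ripple band, then
#' marks maximal runs where the Hilbert envelope of the band-passed signal
#' exceeds the threshold as events of interest (EoI). Runs closer than
#' `merge_gap_ms` merge; runs failing `min_duration_ms` or
#' `min_oscillations` are dropped.
#'
#' @param x one bipolar channel, raw (unfiltered), in microvolts.
#' @param fs sampling rate in Hz.
#' @param cfg [detector_config()].
#' @return data.frame with `onset_sample`, `offset_sample` (half-open,
#'   1-based onset), `peak_envelope_uv`; the detection threshold is
#'   attached as attribute `threshold`, the band-passed trace as attribute
#'   is not retained.
#' @export
stage1_detect <- function(x, fs, cfg = detector_config()) {
  xb <- bandpass_ripple(x, fs, cfg$band_hz)
  env <- hilbert_envelope(xb)
  ent <- stockwell_entropy(x, fs, cfg$entropy_window_s, cfg$band_hz,
                           cfg$freq_step_hz)
  thr_q <- stats::quantile(ent$entropy, cfg$baseline_entropy_quantile,
                           names = FALSE, type = 7)
  base_win <- which(ent$entropy >= thr_q)
  if (!length(base_win))
    stop("baseline error: no high-entropy baseline window found")
  wlen <- round(cfg$entropy_window_s * fs)
  wmax <- vapply(base_win, function(w)
    max(env[((w - 1) * wlen + 1):(w * wlen)]), 0)
  threshold <- cfg$threshold_multiplier * stats::median(wmax)

  ev <- runs_above(env > threshold)
  if (nrow(ev) > 1) {
    gap <- round(cfg$merge_gap_ms / 1000 * fs)
    keep <- list(ev[1, ])
    for (i in 2:nrow(ev)) {
      last <- keep[[length(keep)]]
      if (ev[i, 1] - last[2] < gap) {
        last[2] <- ev[i, 2]
        keep[[length(keep)]] <- last
      } else keep[[length(keep) + 1]] <- ev[i, ]
    }
    ev <- do.call(rbind, keep)
  }
  if (nrow(ev)) {
    min_len <- cfg$min_duration_ms / 1000 * fs
    ok <- logical(nrow(ev))
    peak <- numeric(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      seg <- xb[ev[i, 1]:(ev[i, 2] - 1)]
      peak[i] <- max(env[ev[i, 1]:(ev[i, 2] - 1)])
      nosc <- count_oscillations(seg, threshold / 2)
      ok[i] <- (ev[i, 2] - ev[i, 1]) >= min_len && nosc >= cfg$min_oscillations
    }
    ev <- ev[ok, , drop = FALSE]
    peak <- peak[ok]
  } else peak <- numeric(0)
  out <- data.frame(onset_sample = ev[, 1], offset_sample = ev[, 2],
                    peak_envelope_uv = peak)
  attr(out, "threshold") <- threshold
  out
}

count_oscillations <- function(seg, level) {
  # local maxima of the rectified band-passed trace above `level`
  a <- abs(seg)
  n <- length(a)
  if (n < 3) return(0)
  pk <- a[2:(n - 1)] > a[1:(n - 2)] & a[2:(n - 1)] >= a[3:n] &
    a[2:(n - 1)] > level
  sum(pk)
}

#' Stage II: isolated high-frequency peak in time-frequency space
#'
#' Computes the time-averaged Stockwell power profile over the event and
#' keeps it iff the ripple-band peak is separated from the low-frequency
#' (<40 Hz) power maximum by a spectral trough whose power is at most
#' `stage2_trough_ratio` times the ripple-peak power (boundary inclusive).
#' Band-limited transients whose spectrum decays monotonically (filtered
#' spikes) exhibit no such trough and are rejected.
#'
#' @param onset_sample,offset_sample event span (half-open) in samples.
#' @param x raw channel signal containing the event.
#' @param fs sampling rate in Hz.
#' @param cfg [detector_config()].
#' @return logical: keep (TRUE) or reject (FALSE).
#' @export
stage2_isolated_peak <- function(onset_sample, offset_sample, x, fs,
                                 cfg = detector_config()) {
  pad <- round(0.25 * fs)
  a <- max(1, onset_sample - pad)
  b <- min(length(x), offset_sample + pad)
  seg <- x[a:b]
  freqs <- seq(4, cfg$band_hz[2], by = 4)
  S <- stockwell_transform(seg, fs, freqs)
  ev_cols <- (onset_sample - a + 1):(offset_sample - a)
  prof <- rowMeans(Mod(S[, ev_cols, drop = FALSE])^2)
  hf <- which(freqs >= cfg$band_hz[1])
  lf <- which(freqs < 40)
  i_hf <- hf[which.max(prof[hf])]
  i_lf <- lf[which.max(prof[lf])]
  between <- (i_lf + 1):(i_hf - 1)
  if (length(between) < 1) return(FALSE)
  trough <- min(prof[between])
  trough <= cfg$stage2_trough_ratio * prof[i_hf]
}

#' Stage III: scalp-specific rejection
#'
#' Applies the published scalp criteria to candidate events carrying
#' `amplitude_uv` and `snr`: events with amplitude >= 40 uV are
#' `rejected_amplitude`, events with SNR < 4 are `rejected_snr`, and events
#' co-occurring (partial overlap in time, i.e. at least one shared sample
#' on half-open spans) with any candidate on the homologous contralateral
#' channel are `rejected_bilateral` -- both partners are rejected.
#' Channels without a distinct homologue (midline and cross-midline
#' derivations) cannot be bilateral-rejected. Amplitude takes precedence
#' over SNR over bilateral when labelling multiply-failing events, but the
#' bilateral co-occurrence check itself considers every candidate
#' regardless of its other flags.
#'
#' @param events data.frame with `channel`, `onset_s`, `offset_s`,
#'   `amplitude_uv`, `snr` (and optionally a prior `status`).
#' @param cfg [detector_config()].
#' @return `events` with a `status` column set to one of `accepted`,
#'   `rejected_amplitude`, `rejected_snr`, `rejected_bilateral` (statuses
#'   other than "candidate" already present, e.g. `rejected_edge`, are kept).
#' @export
stage3_scalp_filter <- function(events, cfg = detector_config()) {
  n <- nrow(events)
  if (!n) {
    events$status <- character(0)
    return(events)
  }
  if (is.null(events$status)) events$status <- rep("candidate", n)
  hom <- homologous_channel(events$channel)
  bilateral <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(hom[i])) next
    j <- which(canonical_bipolar(events$channel) == hom[i])
    if (!length(j)) next
    bilateral[i] <- any(events$onset_s[j] < events$offset_s[i] &
                          events$offset_s[j] > events$onset_s[i])
  }
  status <- events$status
  todo <- status == "candidate"
  status[todo & events$amplitude_uv >= cfg$amplitude_reject_uv] <- "rejected_amplitude"
  todo <- status == "candidate"
  status[todo & events$snr < cfg$snr_reject] <- "rejected_snr"
  todo <- status == "candidate"
  status[todo & bilateral] <- "rejected_bilateral"
  status[status == "candidate"] <- "accepted"
  events$status <- status
  events
}

#' Run the full three-stage HFO detector
#'
#' For every analysis interval and bipolar channel: Stage I marks events of
#' interest against a Stockwell-entropy baseline, Stage II requires an
#' isolated high-frequency peak in time-frequency space, event features
#' (crest frequency, above-threshold duration, peak-to-peak amplitude, SNR
#' against 0.5-s flanks) are measured, and Stage III applies the scalp
#' rejection rules across channels. The result is deterministic for fixed
#' input and configuration.
#'
#' @param rec `eeg_recording`; electrode-space input is re-referenced with
#'   [make_bipolar_montage()] first, bipolar-space input (e.g. from the
#'   simulator) is used as-is.
#' @param intervals data.frame from [select_intervals()]; defaults to one
#'   interval covering the whole record.
#' @param cfg [detector_config()].
#' @return data.frame of class `hfo_events`: `channel`, `interval_index`,
#'   `onset_s`, `offset_s`, `duration_ms`, `frequency_hz`, `amplitude_uv`,
#'   `snr`, `status`. Only `status == "accepted"` events are HFOs.
#' @export
detect_hfo <- function(rec, intervals = NULL, cfg = detector_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$space == "electrode") rec <- make_bipolar_montage(rec)
  if (is.null(intervals))
    intervals <- data.frame(index = 1L, start_s = 0,
                            end_s = recording_duration(rec), stage = NA)
  if (!nrow(intervals)) stop("at least one interval required")
  fs <- rec$fs_hz
  all_events <- list()
  for (k in seq_len(nrow(intervals))) {
    i0 <- round(intervals$start_s[k] * fs) + 1
    i1 <- round(intervals$end_s[k] * fs)
    cand <- list()
    for (ch in rec$labels) {
      x <- rec$samples[ch, i0:i1]
      eoi <- tryCatch(stage1_detect(x, fs, cfg),
                      error = function(e) {
                        if (grepl("baseline error", conditionMessage(e)))
                          return(NULL)
                        stop(e)
                      })
      if (is.null(eoi) || !nrow(eoi)) next
      thr <- attr(eoi, "threshold")
      xb <- bandpass_ripple(x, fs, cfg$band_hz)
      for (i in seq_len(nrow(eoi))) {
        on <- eoi$onset_sample[i]; off <- eoi$offset_sample[i]
        if (!stage2_isolated_peak(on, off, x, fs, cfg)) {
          cand[[length(cand) + 1]] <- event_row(ch, k, i0, on, off, fs,
                                                xb, thr, cfg,
                                                status = "rejected_stage2")
          next
        }
        cand[[length(cand) + 1]] <- event_row(ch, k, i0, on, off, fs, xb,
                                              thr, cfg, status = "candidate")
      }
    }
    if (!length(cand)) next
    ev <- do.call(rbind, cand)
    ev <- stage3_scalp_filter(ev, cfg)
    all_events[[length(all_events) + 1]] <- ev
  }
  out <- if (length(all_events)) do.call(rbind, all_events) else
    data.frame(channel = character(0), interval_index = integer(0),
               onset_s = numeric(0), offset_s = numeric(0),
               duration_ms = numeric(0), frequency_hz = numeric(0),
               amplitude_uv = numeric(0), snr = numeric(0),
               status = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hfo_events", class(out))
  out
}

event_row <- function(ch, interval_k, i0, on, off, fs, xb, threshold, cfg,
                      status) {
  seg <- xb[on:(off - 1)]
  freq <- tryCatch(event_frequency(seg, fs, band = cfg$band_hz),
                   error = function(e) NA_real_)
  amp <- event_amplitude(seg)
  snr <- event_snr(xb, on, off, fs, flank_s = cfg$flank_s,
                   min_flank_s = cfg$min_flank_s)
  if (is.na(snr) && status == "candidate") status <- "rejected_edge"
  data.frame(channel = ch, interval_index = interval_k,
             onset_s = (i0 - 1 + on - 1) / fs,
             offset_s = (i0 - 1 + off - 1) / fs,
             duration_ms = (off - on) / fs * 1000,
             frequency_hz = freq, amplitude_uv = amp, snr = snr,
             status = status, stringsAsFactors = FALSE)
}
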
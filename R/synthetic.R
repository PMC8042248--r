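# Synthetic scalp-EEG simulator: N3-like background (1/f noise with
# slow-wave and spindle components) in bipolar channel space, plus injected
# ripple events and decoy artifacts with a ground-truth table, so the whole
# detection pipeline is testable without any recorded data.

#' Simulator configuration
#'
#' The simulator works directly in bipolar derivation space: each channel
#' receives an independent background realization and events are injected
#' at the named derivation, which avoids committing to a volume-conduction
#' model. The background is 1/f-weighted noise (exponent 1) scaled so that
#' its ripple-band (80-250 Hz) RMS matches `background_rms_uv` as measured
#' by the package's own band-pass filter, plus slow-wave (0.5-2 Hz) and
#' spindle (11-15 Hz) components that are negligible in-band.
#'
#' @param labels bipolar channel names (default: all 52 derivations).
#' @param fs_hz sampling rate (default 1024; must exceed 500).
#' @param duration_s record length in seconds.
#' @param background_rms_uv target ripple-band RMS per channel (default
#'   1.5 uV, an N3-like scalp value).
#' @param slow_amp_uv,spindle_amp_uv component amplitudes in uV.
#' @param oneover_f_exponent spectral exponent of the broadband noise.
#' @param seed integer; fully determines the output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(labels = bipolar_adjacency_1020()$name,
                       fs_hz = 1024, duration_s = 300,
                       background_rms_uv = 1.5,
                       slow_amp_uv = 30, spindle_amp_uv = 8,
                       oneover_f_exponent = 1, seed = 1) {
  if (duration_s <= 0) stop("invalid-config error: duration_s must be > 0")
  if (fs_hz <= 500) stop("invalid-config error: fs_hz must exceed 500 (Nyquist for 250 Hz)")
  if (background_rms_uv <= 0) stop("invalid-config error: background_rms_uv must be > 0")
  structure(list(labels = labels, fs_hz = fs_hz, duration_s = duration_s,
                 background_rms_uv = background_rms_uv,
                 slow_amp_uv = slow_amp_uv, spindle_amp_uv = spindle_amp_uv,
                 oneover_f_exponent = oneover_f_exponent, seed = seed),
            class = "sim_config")
}

spectral_noise <- function(n, fs, exponent) {
  # real 1/f^exponent noise via hermitian spectral synthesis
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  w <- pmax(f, 0.5)^(-exponent / 2)
  amp <- stats::rnorm(nf) * w
  phase <- stats::runif(nf, 0, 2 * pi)
  X <- complex(modulus = abs(amp), argument = phase)
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1)] <- X
  if (n %% 2 == 0) {
    spec[nf + 1] <- complex(real = Re(X[nf]))
    spec[(nf + 2):n] <- Conj(X[(nf - 1):1])
  } else {
    spec[(nf + 2):n] <- Conj(X[nf:1])
  }
  Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
}

#' Generate an N3-like background recording
#'
#' @param config [sim_config()].
#' @return bipolar-space `eeg_recording` annotated as one continuous N3
#'   span; every channel's ripple-band RMS (band-pass filter then RMS) is
#'   within a few percent of `background_rms_uv`.
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$fs_hz
  n <- round(config$duration_s * fs)
  t <- (0:(n - 1)) / fs
  out <- matrix(0, length(config$labels), n)
  for (ci in seq_along(config$labels)) {
    x <- spectral_noise(n, fs, config$oneover_f_exponent)
    rms_band <- sqrt(mean(bandpass_ripple(x, fs)^2))
    x <- x * config$background_rms_uv / rms_band
    # slow waves: three random tones in 0.5-2 Hz
    for (k in 1:3) {
      f0 <- stats::runif(1, 0.5, 2)
      x <- x + config$slow_amp_uv / 3 *
        sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
    }
    # sleep spindles: ~3 one-second 11-15 Hz bursts per minute
    n_sp <- max(1, round(config$duration_s / 20))
    for (k in seq_len(n_sp)) {
      on <- sample.int(max(1, n - fs), 1)
      len <- round(stats::runif(1, 0.5, 1.5) * fs)
      len <- min(len, n - on)
      f0 <- stats::runif(1, 11, 15)
      tt <- (0:(len - 1)) / fs
      x[on:(on + len - 1)] <- x[on:(on + len - 1)] +
        config$spindle_amp_uv * tukey_window(len) *
        sin(2 * pi * f0 * tt + stats::runif(1, 0, 2 * pi))
    }
    out[ci, ] <- x
  }
  ann <- data.frame(onset_s = 0, duration_s = config$duration_s,
                    label = "N3", stringsAsFactors = FALSE)
  eeg_recording(out, fs, config$labels, annotations = ann, space = "bipolar")
}

#' Tukey (tapered cosine) window
#' @param n window length in samples.
#' @param alpha taper fraction (default 0.5).
#' @return numeric vector of length `n`.
#' @export
tukey_window <- function(n, alpha = 0.5) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

ripple_waveform <- function(fs, frequency_hz, duration_ms, amplitude_uv) {
  len <- max(2, round(duration_ms / 1000 * fs))
  tt <- (0:(len - 1)) / fs
  amplitude_uv / 2 * tukey_window(len) * sin(2 * pi * frequency_hz * tt)
}

#' Draw a random ground-truth event table
#'
#' Event parameters emulate the published per-patient ranges: frequency
#' uniform in `freq_range`, duration uniform in `duration_range` and
#' peak-to-peak amplitude as given. Onsets are spaced at least `min_gap_s`
#' apart and away from the record edges so that SNR flanks are clean.
#' Bilateral artifacts are emitted as single rows (one of the pair);
#' [inject_events()] expands them into homologous pairs.
#'
#' @param labels channels to draw from (bilateral artifacts only use
#'   channels with a distinct homologue).
#' @param duration_s record length the events must fit in.
#' @param n_ripple,n_amp_artifact,n_bilateral event counts per kind.
#' @param ripple_amplitude_uv peak-to-peak amplitude of true ripples
#'   (default 15 uV); may be a vector to sample from.
#' @param artifact_amplitude_uv amplitude of high-amplitude decoys
#'   (default 55 uV, above the 40 uV rejection ceiling).
#' @param bilateral_amplitude_uv amplitude of bilateral decoys (default
#'   30 uV: below the amplitude ceiling, so only the co-occurrence rule can
#'   reject them, and strong enough to be detected on both hemispheres).
#' @param freq_range,duration_range ripple parameter ranges.
#' @param min_gap_s minimum onset spacing (default 2 s).
#' @return data.frame `channel`, `onset_s`, `duration_ms`, `frequency_hz`,
#'   `amplitude_uv`, `kind`.
#' @export
random_events <- function(labels, duration_s, n_ripple = 10,
                          n_amp_artifact = 0, n_bilateral = 0,
                          ripple_amplitude_uv = 15,
                          artifact_amplitude_uv = 55,
                          bilateral_amplitude_uv = 30,
                          freq_range = c(90, 200),
                          duration_range = c(30, 60),
                          min_gap_s = 2) {
  n <- n_ripple + n_amp_artifact + n_bilateral
  if (n == 0)
    return(data.frame(channel = character(0), onset_s = numeric(0),
                      duration_ms = numeric(0), frequency_hz = numeric(0),
                      amplitude_uv = numeric(0), kind = character(0)))
  slots <- seq(1, duration_s - 1.5, by = min_gap_s)
  if (length(slots) < n) stop("record too short for requested events")
  onset <- sort(sample(slots, n)) + stats::runif(n, 0, min_gap_s / 4)
  kind <- c(rep("ripple", n_ripple),
            rep("high_amplitude_artifact", n_amp_artifact),
            rep("bilateral_artifact", n_bilateral))
  kind <- sample(kind)
  lat <- labels[!is.na(homologous_channel(labels))]
  ch <- ifelse(kind == "bilateral_artifact",
               sample(lat, n, replace = TRUE),
               sample(labels, n, replace = TRUE))
  amp <- sample(rep(ripple_amplitude_uv, 2), n, replace = TRUE)
  amp[kind == "high_amplitude_artifact"] <-
    sample(rep(artifact_amplitude_uv, 2), sum(kind == "high_amplitude_artifact"),
           replace = TRUE)
  amp[kind == "bilateral_artifact"] <-
    sample(rep(bilateral_amplitude_uv, 2), sum(kind == "bilateral_artifact"),
           replace = TRUE)
  data.frame(channel = ch, onset_s = onset,
             duration_ms = stats::runif(n, duration_range[1], duration_range[2]),
             frequency_hz = stats::runif(n, freq_range[1], freq_range[2]),
             amplitude_uv = amp, kind = kind, stringsAsFactors = FALSE)
}

#' Inject events into a recording
#'
#' Each event adds a Tukey(0.5)-windowed sinusoid of the stated frequency
#' and duration whose peak-to-peak amplitude equals `amplitude_uv` at the
#' named bipolar derivation. Rows of kind `bilateral_artifact` without a
#' partner row are expanded into a time-overlapping pair on the homologous
#' contralateral channel (both rows appear in the returned ground truth).
#' Samples change only inside each event's support.
#'
#' @param rec bipolar-space `eeg_recording`.
#' @param events ground-truth data.frame as from [random_events()].
#' @return list with `recording` (modified copy) and `truth` (the expanded
#'   ground-truth table).
#' @export
inject_events <- function(rec, events) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  dur <- recording_duration(rec)
  events <- as.data.frame(events)
  # expand unpaired bilateral artifacts onto the homologous channel
  bil <- which(events$kind == "bilateral_artifact")
  add <- list()
  for (i in bil) {
    hom <- homologous_channel(events$channel[i])
    if (is.na(hom))
      stop("labeling error: channel ", events$channel[i],
           " has no homologous partner for a bilateral artifact")
    already <- any(events$channel == hom &
                     abs(events$onset_s - events$onset_s[i]) <
                       events$duration_ms[i] / 1000)
    if (!already) {
      row <- events[i, ]
      row$channel <- hom
      add[[length(add) + 1]] <- row
    }
  }
  if (length(add)) events <- rbind(events, do.call(rbind, add))
  events <- events[order(events$onset_s), , drop = FALSE]
  rownames(events) <- NULL

  for (i in seq_len(nrow(events))) {
    ch <- events$channel[i]
    if (!ch %in% rec$labels)
      stop("labeling error: unknown channel ", ch)
    if (events$onset_s[i] < 0 ||
        events$onset_s[i] + events$duration_ms[i] / 1000 > dur)
      stop("bounds error: event ", i, " exceeds record end")
    w <- ripple_waveform(fs, events$frequency_hz[i], events$duration_ms[i],
                         events$amplitude_uv[i])
    i0 <- round(events$onset_s[i] * fs) + 1
    idx <- i0:(i0 + length(w) - 1)
    rec$samples[ch, idx] <- rec$samples[ch, idx] + w
  }
  list(recording = rec, truth = events)
}

#' Generate a synthetic cohort with an age trend
#'
#' Ages are drawn uniformly over `age_range`; the injected HFO rate decays
#' with age (`rate0 * exp(-age / age_tau)`, multiplicative log-normal
#' noise `rate_noise_sd`) and the background ripple-band RMS decreases
#' linearly with age (`rba0 - rba_slope * age`, additive Gaussian noise),
#' emulating the negative rate-age and RBA-age correlations of a
#' paediatric cohort. With `rate_noise_sd = 0` the rate-age law is strictly
#' monotone. Recordings are not materialized here (memory); use
#' [patient_recording()] per patient.
#'
#' @param n_patients number of patients (>= 2).
#' @param seed integer master seed; determines everything.
#' @param age_range years, default `c(0.7, 17.4)`.
#' @param duration_s per-patient record length (default 600 s = two 5-min
#'   intervals).
#' @param labels simulated bipolar channels (default: a mirror-closed
#'   8-derivation sub-montage, to keep cohort simulations desk-sized).
#' @param rate0,age_tau,rate_noise_sd rate-age law parameters (HFO/min at
#'   age 0; decay constant in years; log-normal sd).
#' @param rba0,rba_slope,rba_noise_sd background RMS-age law (uV; uV/year;
#'   additive sd).
#' @return list of class `hfo_cohort`: `meta` (data.frame with
#'   `patient_id`, `age_years`, `true_rate`, `background_rms_uv`,
#'   `focus_channel`, `patient_seed`), `truth` (list of per-patient event
#'   tables), and the generation parameters.
#' @export
generate_cohort <- function(n_patients, seed, age_range = c(0.7, 17.4),
                            duration_s = 600,
                            labels = c("T3-C3", "T4-C4", "F3-C3", "F4-C4",
                                       "T5-P3", "T6-P4", "P3-O1", "P4-O2"),
                            rate0 = 5, age_tau = 5, rate_noise_sd = 0.5,
                            rba0 = 1.9, rba_slope = 0.05,
                            rba_noise_sd = 0.08) {
  if (n_patients < 2) stop("invalid-config error: n_patients must be >= 2")
  set.seed(seed)
  age <- sort(stats::runif(n_patients, age_range[1], age_range[2]))
  true_rate <- rate0 * exp(-age / age_tau) *
    exp(stats::rnorm(n_patients, 0, rate_noise_sd))
  rms <- pmin(pmax(rba0 - rba_slope * age +
                     stats::rnorm(n_patients, 0, rba_noise_sd), 0.8), 2.5)
  focus <- sample(labels, n_patients, replace = TRUE)
  pseed <- sample.int(1e9, n_patients)
  minutes <- duration_s / 60
  truth <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    set.seed(pseed[i])
    n_ev <- max(0, round(true_rate[i] * minutes))
    truth[[i]] <- if (n_ev > 0) {
      ev <- random_events(labels, duration_s, n_ripple = n_ev,
                          ripple_amplitude_uv = stats::runif(n_ev, 12, 25),
                          freq_range = pmin(pmax(c(110, 160) - 2 * age[i], 85),
                                            200))
      ev$channel <- focus[i]
      ev
    } else random_events(labels, duration_s, n_ripple = 0)
  }
  structure(list(
    meta = data.frame(patient_id = seq_len(n_patients), age_years = age,
                      true_rate = true_rate, background_rms_uv = rms,
                      focus_channel = focus, patient_seed = pseed,
                      stringsAsFactors = FALSE),
    truth = truth, labels = labels, duration_s = duration_s, seed = seed),
    class = "hfo_cohort")
}

#' Materialize one synthetic patient's recording
#'
#' @param cohort result of [generate_cohort()].
#' @param i patient index.
#' @return list with `recording` (events injected), `truth`, `intervals`
#'   (5-min N3 intervals covering the record) and the patient's meta row.
#' @export
patient_recording <- function(cohort, i) {
  stopifnot(inherits(cohort, "hfo_cohort"))
  m <- cohort$meta[i, ]
  cfg <- sim_config(labels = cohort$labels, duration_s = cohort$duration_s,
                    background_rms_uv = m$background_rms_uv,
                    seed = m$patient_seed + 1)
  bg <- generate_background(cfg)
  inj <- inject_events(bg, cohort$truth[[i]])
  iv <- suppressWarnings(select_intervals(inj$recording))
  list(recording = inj$recording, truth = inj$truth, intervals = iv,
       meta = m)
}

#' Write a synthetic dataset to disk
#'
#' One EDF per patient plus tab-separated ground-truth event tables
#' (`sub-XX_truth.tsv`), sleep-stage sidecars (`sub-XX_events.tsv`) and a
#' cohort metadata table (`participants.tsv`).
#'
#' @param n_patients,seed forwarded to [generate_cohort()].
#' @param out_dir output directory (created if missing).
#' @param ... further arguments to [generate_cohort()].
#' @return `out_dir`, invisibly.
#' @export
simulate_dataset <- function(n_patients, seed, out_dir, ...) {
  co <- generate_cohort(n_patients, seed, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_patients)) {
    p <- patient_recording(co, i)
    id <- sprintf("sub-%02d", i)
    write_edf(p$recording, file.path(out_dir, paste0(id, "_eeg.edf")))
    ann <- p$recording$annotations
    utils::write.table(
      data.frame(onset = ann$onset_s, duration = ann$duration_s,
                 trial_type = ann$label),
      file.path(out_dir, paste0(id, "_events.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(p$truth,
                       file.path(out_dir, paste0(id, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(co$meta, file.path(out_dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
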
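fs <- 1024

test_that("channel rates reproduce the count-over-minutes arithmetic", {
  ev <- data.frame(channel = rep("P3-O1", 397), status = "accepted")
  cr <- channel_rates(ev, minutes = 30)
  expect_equal(round(cr$rate, 1), 13.2)          # 397 / 30
  cr2 <- channel_rates(data.frame(channel = rep("T6-P4", 137),
                                  status = "accepted"), minutes = 20)
  expect_equal(round(cr2$rate, 1), 6.8)          # 137 / 20 = 6.85
  empty <- channel_rates(data.frame(channel = character(0),
                                    status = character(0)),
                         minutes = 30, channels = "P3-O1")
  expect_equal(empty$rate, 0)
  expect_error(channel_rates(ev, minutes = 0), "division error")
  # rate x minutes is integral
  set.seed(1)
  n <- sample(1:500, 1)
  cr3 <- channel_rates(data.frame(channel = rep("F3-C3", n),
                                  status = "accepted"), minutes = 35)
  expect_equal(cr3$rate * cr3$total_minutes, round(cr3$rate * cr3$total_minutes))
})

test_that("crest-interval frequency matches pure tones and chirps", {
  t <- (0:round(0.05 * fs)) / fs
  expect_equal(event_frequency(sin(2 * pi * 100 * t), fs), 100, tolerance = 1 / 100)
  t2 <- (0:round(0.04 * fs)) / fs
  expect_equal(event_frequency(sin(2 * pi * 250 * t2), fs), 250, tolerance = 2 / 250)
  # linear chirp 90 -> 110 Hz: crest spacing estimates the mean instantaneous freq
  dur <- 0.1
  tt <- seq(0, dur, by = 1 / fs)
  phase <- 2 * pi * (90 * tt + 0.5 * (110 - 90) / dur * tt^2)
  expect_equal(event_frequency(sin(phase), fs), 100, tolerance = 3 / 100)
  expect_error(event_frequency(rep(0, 100), fs), "undefined-frequency")
})

test_that("duration is the length of the threshold-exceeding run", {
  expect_equal(event_duration(1, 42, 1024), 41 / 1024 * 1000)
  expect_equal(round(event_duration(1, 42, 1024)), 40)
  # rectangular burst: envelope crossing recovers the support within a sample
  x <- numeric(fs)
  len <- round(0.024 * fs)
  x[500:(500 + len - 1)] <- sin(2 * pi * 150 * (0:(len - 1)) / fs)
  env <- hilbert_envelope(x)
  run <- range(which(env > 0.5))
  expect_equal((run[2] - run[1] + 1) / fs * 1000, 24, tolerance = 2)
})

test_that("amplitude is the highest adjacent crest-trough swing", {
  t <- (0:999) / fs
  expect_equal(event_amplitude(10 * sin(2 * pi * 100 * t)), 20, tolerance = 0.01)
  decay <- 8 * exp(-t * 50) * sin(2 * pi * 100 * t)
  expect_equal(event_amplitude(decay), max(decay) - min(decay), tolerance = 0.5)
  # asymmetric wave: crest +12, trough -5
  asym <- c(0, 12, -5, 2, 0)
  expect_equal(event_amplitude(asym), 17)
})

test_that("SNR is the event-to-flank power ratio with documented sentinels", {
  x <- rep(1, fs * 3)                       # constant power everywhere
  expect_equal(event_snr(x, fs + 1, fs + 513, fs), 1, tolerance = 1e-9)
  # sinusoid of amplitude A on white noise sigma: SNR ~ (A^2/2 + s^2)/s^2
  set.seed(4)
  A <- 5; sigma <- 1
  y <- rnorm(3 * fs, sd = sigma)
  ev <- (fs + 1):(2 * fs)
  y[ev] <- y[ev] + A * sin(2 * pi * 130 * (seq_along(ev) - 1) / fs)
  got <- event_snr(y, fs + 1, 2 * fs + 1, fs)
  expect_equal(got, (A^2 / 2 + sigma^2) / sigma^2, tolerance = 0.1)
  # silent flanks with a non-silent event: infinite-SNR sentinel with warning
  z <- numeric(3 * fs)
  z[ev] <- 1
  expect_warning(s <- event_snr(z, fs + 1, 2 * fs + 1, fs), "zero flank")
  expect_identical(s, Inf)
  # insufficient flank near the interval edge
  expect_true(is.na(event_snr(y, 10, 200, fs)))
})

test_that("RBA equals A/sqrt(2) for an in-band tone and the noise-gain oracle", {
  t <- (0:(fs * 600 - 1)) / fs
  x <- 2 * sin(2 * pi * 120 * t)
  iv <- data.frame(index = 1:2, start_s = c(0, 300), end_s = c(300, 600))
  expect_equal(ripple_band_activity(x, iv, fs), 2 / sqrt(2), tolerance = 0.01)
  expect_equal(ripple_band_activity(numeric(fs * 600), iv, fs), 0)
  # white noise: RMS gain predicted from the filter's frequency response
  set.seed(9)
  sigma <- 2
  noise <- rnorm(fs * 600, sd = sigma)
  bf <- signal::butter(6, c(80, 250) / (fs / 2), type = "pass")
  H <- signal::freqz(bf, n = 4096, Fs = fs)
  g <- sqrt(mean(Mod(H$h)^4))               # filtfilt applies |H|^2
  got <- ripple_band_activity(noise, iv, fs)
  expect_equal(got, g * sigma, tolerance = 0.05 * g * sigma)
})

test_that("patient summaries follow the top-channel and morphology rules", {
  iv <- data.frame(index = 1:2, start_s = c(0, 300), end_s = c(300, 600))
  ev <- data.frame(channel = c(rep("P3-O1", 4), rep("F3-C3", 2)),
                   onset_s = 1:6, offset_s = 1:6 + 0.05,
                   duration_ms = 50, frequency_hz = 100,
                   amplitude_uv = 12, snr = 8, status = "accepted")
  s <- summarize_patient(ev, iv)
  expect_equal(s$top_channel, "P3-O1")
  expect_equal(s$rate_top, 4 / 10)
  expect_true(s$morphology_valid)           # 6 accepted events > 3
  expect_equal(s$mean_frequency_hz, 100)
  # exactly 3 events: below the morphology threshold
  s3 <- summarize_patient(ev[1:3, ], iv)
  expect_false(s3$morphology_valid)
  expect_true(is.na(s3$mean_frequency_hz))
  # tie on rate: higher count impossible, so lexicographic channel name
  tie <- data.frame(channel = c("P4-O2", "F3-C3"), onset_s = c(1, 2),
                    offset_s = c(1.05, 2.05), duration_ms = 50,
                    frequency_hz = 100, amplitude_uv = 12, snr = 8,
                    status = "accepted")
  expect_equal(summarize_patient(tie, iv)$top_channel, "F3-C3")
})

test_that("injected event parameters are recoverable at high SNR", {
  labs <- c("F3-C3", "F4-C4")
  cfg <- sim_config(labels = labs, duration_s = 180, seed = 9)
  bg <- generate_background(cfg)
  set.seed(21)
  ev <- random_events(labs, 180, n_ripple = 15,
                      ripple_amplitude_uv = runif(15, 25, 35),
                      duration_range = c(30, 60))
  inj <- inject_events(bg, ev)
  det <- detect_hfo(inj$recording)
  acc <- det[det$status == "accepted", ]
  expect_true(all(acc$snr >= 6))
  inj_f <- est_f <- err_f <- err_d <- err_a <- numeric(0)
  for (i in seq_len(nrow(inj$truth))) {
    tr <- inj$truth[i, ]
    j <- which(acc$channel == tr$channel &
                 acc$onset_s < tr$onset_s + tr$duration_ms / 1000 &
                 acc$offset_s > tr$onset_s)
    if (!length(j)) next
    inj_f <- c(inj_f, tr$frequency_hz)
    est_f <- c(est_f, acc$frequency_hz[j[1]])
    err_f <- c(err_f, acc$frequency_hz[j[1]] - tr$frequency_hz)
    err_d <- c(err_d, acc$duration_ms[j[1]] - tr$duration_ms)
    err_a <- c(err_a, (acc$amplitude_uv[j[1]] - tr$amplitude_uv) /
                 tr$amplitude_uv)
  }
  expect_gte(length(err_f), 10)
  expect_lte(median(abs(err_f)), 5)
  expect_lte(median(abs(err_d)), 10)
  expect_lte(median(abs(err_a)), 0.10)
  # injected vs estimated frequency track each other tightly
  expect_gt(cor(inj_f, est_f), 0.95)
})
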
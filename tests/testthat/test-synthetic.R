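test_that("the seed fully determines the simulated recording", {
  cfg <- sim_config(labels = small_montage, duration_s = 10, seed = 1)
  a <- generate_background(cfg)
  b <- generate_background(cfg)
  expect_identical(a$samples, b$samples)
  c2 <- generate_background(sim_config(labels = small_montage,
                                       duration_s = 10, seed = 2))
  expect_false(identical(a$samples, c2$samples))
})

test_that("background ripple-band RMS hits the configured target on every channel", {
  cfg <- sim_config(duration_s = 60, background_rms_uv = 1.5, seed = 1)
  bg <- generate_background(cfg)
  expect_equal(nrow(bg$samples), 21 + 31)  # all 52 derivations
  rms <- apply(bg$samples, 1, function(v)
    sqrt(mean(bandpass_ripple(v, cfg$fs_hz)^2)))
  expect_true(all(rms >= 1.35 & rms <= 1.65))
})

test_that("degenerate simulator configs are rejected", {
  expect_error(sim_config(duration_s = 0), "invalid-config")
  expect_error(sim_config(fs_hz = 400), "invalid-config")
  expect_error(sim_config(background_rms_uv = -1), "invalid-config")
})

test_that("injecting an empty event list is the identity", {
  cfg <- sim_config(labels = small_montage, duration_s = 5, seed = 1)
  bg <- generate_background(cfg)
  out <- inject_events(bg, random_events(small_montage, 5, n_ripple = 0))
  expect_identical(out$recording$samples, bg$samples)
})

test_that("injected ripple peak-to-peak amplitude is calibrated in-band", {
  fs <- 1024
  silent <- eeg_recording(matrix(0, 1, fs * 4), fs, "P3-O1",
                          space = "bipolar")
  ev <- data.frame(channel = "P3-O1", onset_s = 2, duration_ms = 50,
                   frequency_hz = 100, amplitude_uv = 15, kind = "ripple")
  out <- inject_events(silent, ev)
  xb <- bandpass_ripple(out$recording$samples[1, ], fs)
  p2p <- max(xb) - min(xb)
  expect_gt(p2p, 15 * 0.95)
  expect_lt(p2p, 15 * 1.05)
})

test_that("injection modifies samples only inside the event support", {
  cfg <- sim_config(labels = small_montage, duration_s = 10, seed = 3)
  bg <- generate_background(cfg)
  ev <- data.frame(channel = "F3-C3", onset_s = 4, duration_ms = 60,
                   frequency_hz = 120, amplitude_uv = 20, kind = "ripple")
  out <- inject_events(bg, ev)
  d <- out$recording$samples - bg$samples
  expect_true(all(d[rownames(d) != "F3-C3", ] == 0))
  idx_changed <- which(d["F3-C3", ] != 0)
  fs <- cfg$fs_hz
  expect_gte(min(idx_changed), round(4 * fs) + 1)
  expect_lte(max(idx_changed), round(4 * fs) + round(0.060 * fs) + 1)
})

test_that("bilateral artifacts come as homologous time-overlapping pairs", {
  cfg <- sim_config(labels = c("T3-F3", "T4-F4"), duration_s = 10, seed = 3)
  bg <- generate_background(cfg)
  ev <- data.frame(channel = "T3-F3", onset_s = 5, duration_ms = 80,
                   frequency_hz = 130, amplitude_uv = 25,
                   kind = "bilateral_artifact")
  out <- inject_events(bg, ev)
  expect_equal(nrow(out$truth), 2)
  partner <- out$truth[out$truth$channel == "T4-F4", ]
  expect_equal(nrow(partner), 1)
  expect_lt(abs(partner$onset_s - 5), partner$duration_ms / 1000)
})

test_that("events violating channel or bounds invariants are rejected", {
  cfg <- sim_config(labels = small_montage, duration_s = 5, seed = 1)
  bg <- generate_background(cfg)
  bad_ch <- data.frame(channel = "Xx-Yy", onset_s = 1, duration_ms = 50,
                       frequency_hz = 100, amplitude_uv = 10, kind = "ripple")
  expect_error(inject_events(bg, bad_ch), "labeling error")
  bad_t <- data.frame(channel = "F3-C3", onset_s = 4.99, duration_ms = 50,
                      frequency_hz = 100, amplitude_uv = 10, kind = "ripple")
  expect_error(inject_events(bg, bad_t), "bounds error")
})

test_that("cohort generation produces the requested shape and age laws", {
  co <- generate_cohort(30, seed = 7)
  expect_equal(nrow(co$meta), 30)
  expect_true(all(co$meta$age_years >= 0.7 & co$meta$age_years <= 17.4))
  expect_length(co$truth, 30)
  expect_error(generate_cohort(1, seed = 1), "invalid-config")
  # zero noise + strictly monotone decay law: perfect negative rank correlation
  co0 <- generate_cohort(30, seed = 7, rate_noise_sd = 0)
  expect_equal(spearman(co0$meta$age_years, co0$meta$true_rate)$r, -1)
})

test_that("the injected rate-age trend is negative across seeds", {
  neg <- vapply(1:100, function(s) {
    co <- generate_cohort(30, seed = s)
    spearman(co$meta$age_years, co$meta$true_rate)$r < 0
  }, TRUE)
  expect_gte(mean(neg), 0.95)
})
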
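# Shared fixtures: small bipolar montages and injected-ripple recordings
# built in code so no binary data ships with the package.

quiet_intervals <- function(rec) suppressWarnings(select_intervals(rec))

small_montage <- c("F3-C3", "F4-C4", "P3-O1", "P4-O2")

# one 5-min 4-channel background with n injected 15-uV ripples; memoized per
# test file run to keep the suite fast
make_ripple_recording <- function(seed_bg = 5, seed_ev = 11, n_ripple = 10,
                                  amplitude = 15, duration_s = 300,
                                  labels = small_montage, ...) {
  cfg <- sim_config(labels = labels, duration_s = duration_s, seed = seed_bg)
  bg <- generate_background(cfg)
  set.seed(seed_ev)
  ev <- random_events(labels, duration_s, n_ripple = n_ripple,
                      ripple_amplitude_uv = amplitude, ...)
  inject_events(bg, ev)
}

# brute-force Spearman: mid-ranks then Pearson product-moment on the ranks
spearman_bruteforce <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# brute-force pairwise concordance of block top channels
reliability_bruteforce <- function(tops) {
  n <- length(tops)
  agree <- 0; total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    same <- (is.na(tops[i]) && is.na(tops[j])) ||
      (!is.na(tops[i]) && !is.na(tops[j]) && tops[i] == tops[j])
    if (same) agree <- agree + 1
  }
  100 * agree / total
}
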
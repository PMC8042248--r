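#' Load the packaged per-patient cohort table
#'
#' Thirty patients with age, epilepsy classification, aetiology, CSWS flag,
#' seizure frequency, analyzed intervals, HFO counts and rates, morphology
#' means (frequency, duration, amplitude), SNR, ripple-band activity, top
#' channel and 10-min test-retest reliability (missing for the four
#' patients with insufficient data). Values are as printed in the study's
#' per-patient summary (one decimal / integer precision).
#'
#' @return data.frame, 30 rows.
#' @export
load_cohort_table <- function() {
  path <- system.file("extdata", "table1.tsv", package = "scalpHFO",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Median and interquartile range
#'
#' Missing values are dropped; quantiles use linear interpolation between
#' order statistics (type 7).
#' @param values numeric vector with at least one finite value.
#' @return list with `median` and `iqr`.
#' @export
median_iqr <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("median_iqr: no finite values")
  list(median = stats::median(values),
       iqr = unname(diff(stats::quantile(values, c(0.25, 0.75), type = 7))))
}

#' Spearman rank correlation with tie correction
#'
#' Tie-corrected rank correlation (Pearson correlation of mid-ranks) with a
#' two-sided p-value from the t approximation, as appropriate for tied
#' data.
#' @param x,y numeric vectors of equal length (>= 4 pairwise-complete
#'   pairs).
#' @return list with `r` and `p`.
#' @export
spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("spearman: need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation error: constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Wilcoxon rank-sum test (two independent groups)
#'
#' Two-sided p from the normal approximation with continuity and tie
#' correction.
#' @param a,b numeric vectors (>= 3 each).
#' @return list with `p` and the rank-sum statistic `W`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3)
    stop("wilcoxon_ranksum: need at least 3 values per group")
  if (length(unique(c(a, b))) == 1)
    stop("degenerate-test error: all values tied")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                            correct = TRUE))
  list(p = wt$p.value, W = unname(wt$statistic))
}

#' Wilcoxon signed-rank test (paired)
#'
#' @param a,b paired numeric vectors (>= 5 informative pairs).
#' @return list with `p` and `V`.
#' @export
wilcoxon_signedrank <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 5) stop("wilcoxon_signedrank: need at least 5 pairs")
  if (all(a == b)) stop("degenerate-test error: all differences zero")
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = FALSE, correct = TRUE))
  list(p = wt$p.value, V = unname(wt$statistic))
}

#' Linear model of the HFO rate
#'
#' Ordinary least squares of the per-patient HFO rate on an intercept, the
#' CSWS indicator, the older-age-group indicator (age >= 7 years), the
#' log seizure frequency, and the ripple-band activity. The logarithm
#' defaults to base 10 (base e available for sensitivity analysis).
#'
#' @param table cohort data.frame with columns `rate_hfo_min`, `csws`
#'   ("yes"/"no" or logical), `age_years`, `seizures_per_month` (> 0),
#'   `rba_uv`.
#' @param log_base 10 (default) or `exp(1)`.
#' @return list with `coefficients` (data.frame: term, estimate, ci_low,
#'   ci_high, p) and the underlying `lm` fit.
#' @export
fit_rate_model <- function(table, log_base = 10) {
  stopifnot(all(c("rate_hfo_min", "csws", "age_years", "seizures_per_month",
                  "rba_uv") %in% names(table)))
  if (any(table$seizures_per_month <= 0, na.rm = TRUE))
    stop("seizures_per_month must be positive")
  d <- data.frame(
    rate = table$rate_hfo_min,
    csws_yes = as.numeric(table$csws == "yes" | table$csws == TRUE),
    age_group_older = as.numeric(table$age_years >= 7),
    log_seizure_freq = log(table$seizures_per_month, base = log_base),
    rba = table$rba_uv)
  X <- cbind(1, as.matrix(d[, -1]))
  if (qr(X)$rank < ncol(X))
    stop("model error: rank-deficient design matrix")
  fit <- stats::lm(rate ~ csws_yes + age_group_older + log_seizure_freq + rba,
                   data = d)
  ci <- stats::confint(fit)
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = c("intercept", "csws_yes", "age_group_older",
                               "log_seizure_freq", "rba"),
                      estimate = unname(stats::coef(fit)),
                      ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                      p = unname(sm[, 4]), stringsAsFactors = FALSE)
  list(coefficients = coefs, fit = fit)
}

#' Recompute the cohort statistics from the packaged table
#'
#' Reproduces the cohort-level statistics from the per-patient summary
#' table: total analyzed minutes, rate medians overall and by age group
#' (younger < 7 years vs older >= 7), rank-sum comparisons, the Spearman
#' correlations of HFO characteristics with age, the test-retest
#' reliability summary, and the rate model coefficients. Morphology
#' characteristics (frequency, duration, amplitude, SNR, RBA and their age
#' correlations) are computed over the patients with more than 3 HFOs; the
#' RBA-SNR correlation is computed over all patients.
#'
#' @param table cohort data.frame (defaults to [load_cohort_table()]).
#' @return named list of statistics; `validation` flags row-count or
#'   column problems.
#' @export
reproduce_paper_stats <- function(table = load_cohort_table()) {
  validation <- list(
    n_rows = nrow(table),
    row_count_ok = nrow(table) == 30,
    reliability_missing = sum(is.na(table$reliability_10min_pct)))
  young <- table$age_years < 7
  morph <- table$n_events > 3
  rate <- table$rate_hfo_min
  rel <- table$reliability_10min_pct[!is.na(table$reliability_10min_pct)]
  rm_ <- function(v) median_iqr(v)

  list(
    validation = validation,
    total_minutes = sum(table$n_intervals) * 5,
    n_younger = sum(young), n_older = sum(!young),
    rate_overall = rm_(rate),
    rate_younger = rm_(rate[young]),
    rate_older = rm_(rate[!young]),
    rate_age_group_p = wilcoxon_ranksum(rate[young], rate[!young])$p,
    rate_focal = rm_(rate[table$classification == "focal"]),
    rate_generalized = rm_(rate[table$classification == "generalized"]),
    rate_classification_p = wilcoxon_ranksum(
      rate[table$classification == "focal"],
      rate[table$classification == "generalized"])$p,
    rate_csws = rm_(rate[table$csws == "yes"]),
    frequency = rm_(table$frequency_hz[morph]),
    duration = rm_(table$duration_ms[morph]),
    amplitude = rm_(table$amplitude_uv[morph]),
    snr = rm_(table$snr[morph]),
    rba = rm_(table$rba_uv[morph]),
    spearman_age_frequency = spearman(table$age_years[morph],
                                      table$frequency_hz[morph]),
    spearman_age_duration = spearman(table$age_years[morph],
                                     table$duration_ms[morph]),
    spearman_age_amplitude = spearman(table$age_years[morph],
                                      table$amplitude_uv[morph]),
    spearman_age_snr = spearman(table$age_years[morph], table$snr[morph]),
    spearman_age_rba = spearman(table$age_years[morph], table$rba_uv[morph]),
    spearman_rba_snr = spearman(table$rba_uv, table$snr),
    reliability_10min = rm_(rel),
    reliability_n = length(rel),
    reliability_full_pct = 100 * mean(rel == 100),
    rate_model = fit_rate_model(table)$coefficients)
}
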
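sleep_stage_labels <- function() c("W", "N1", "N2", "N3", "N4", "REM", "R")
artifact_labels <- function() c("artifact", "bad", "BAD", "BAD_segment")

subtract_spans <- function(start, end, cuts) {
  # removes [cut_start, cut_end) spans from [start, end); returns matrix
  segs <- matrix(c(start, end), ncol = 2)
  if (nrow(cuts)) {
    for (i in seq_len(nrow(cuts))) {
      out <- list()
      for (j in seq_len(nrow(segs))) {
        s <- segs[j, 1]; e <- segs[j, 2]
        cs <- max(s, cuts[i, 1]); ce <- min(e, cuts[i, 2])
        if (cs >= ce) { out[[length(out) + 1]] <- c(s, e); next }
        if (s < cs) out[[length(out) + 1]] <- c(s, cs)
        if (ce < e) out[[length(out) + 1]] <- c(ce, e)
      }
      segs <- if (length(out)) do.call(rbind, out) else matrix(numeric(0), ncol = 2)
      if (!nrow(segs)) break
    }
  }
  segs
}

#' Select 5-min analysis intervals from scored sleep
#'
#' Returns non-overlapping intervals of `interval_s` seconds that lie fully
#' inside spans scored as `stage` within the first `first_hours` hours after
#' sleep onset (the start of the first scored non-wake epoch), after
#' removing annotated artifact spans. Each artifact-free stage span is tiled
#' independently from its start; a residual shorter than `interval_s` is
#' discarded. A warning is emitted when fewer than three intervals survive
#' (below the cohort analysis threshold).
#'
#' @param rec `eeg_recording` with sleep-stage annotations.
#' @param stage sleep stage label to analyze (default "N3").
#' @param first_hours restrict to this many hours after sleep onset.
#' @param interval_s interval length in seconds (default 300 = 5 min).
#' @return data.frame with columns `index`, `start_s`, `end_s`, `stage`.
#' @export
select_intervals <- function(rec, stage = "N3", first_hours = 3,
                             interval_s = 300) {
  stopifnot(inherits(rec, "eeg_recording"))
  ann <- rec$annotations
  stages <- ann[ann$label %in% sleep_stage_labels(), , drop = FALSE]
  if (!nrow(stages))
    stop("annotation error: no sleep-stage annotations")
  asleep <- stages[!(stages$label %in% c("W")), , drop = FALSE]
  if (!nrow(asleep))
    stop("annotation error: no non-wake epochs (sleep onset undefined)")
  onset <- min(asleep$onset_s)
  win_end <- onset + first_hours * 3600

  spans <- ann[ann$label == stage, , drop = FALSE]
  arts <- ann[ann$label %in% artifact_labels(), , drop = FALSE]
  cuts <- cbind(arts$onset_s, arts$onset_s + arts$duration_s)

  out <- list()
  if (nrow(spans)) spans <- spans[order(spans$onset_s), , drop = FALSE]
  for (i in seq_len(nrow(spans))) {
    s <- max(spans$onset_s[i], onset)
    e <- min(spans$onset_s[i] + spans$duration_s[i], win_end)
    if (e - s < interval_s) next
    segs <- subtract_spans(s, e, cuts)
    for (j in seq_len(nrow(segs))) {
      n <- floor((segs[j, 2] - segs[j, 1]) / interval_s)
      if (n < 1) next
      st <- segs[j, 1] + (seq_len(n) - 1) * interval_s
      out[[length(out) + 1]] <- data.frame(start_s = st,
                                           end_s = st + interval_s)
    }
  }
  iv <- if (length(out)) do.call(rbind, out) else
    data.frame(start_s = numeric(0), end_s = numeric(0))
  iv <- iv[order(iv$start_s), , drop = FALSE]
  res <- data.frame(index = seq_len(nrow(iv)), start_s = iv$start_s,
                    end_s = iv$end_s,
                    stage = rep(stage, nrow(iv)), stringsAsFactors = FALSE)
  if (nrow(res) < 3)
    warning(sprintf("only %d interval(s) of %g s %s sleep: below the analysis threshold",
                    nrow(res), interval_s, stage))
  res
}

#' Total analyzed minutes of a set of intervals
#' @param intervals data.frame from [select_intervals()].
#' @return minutes.
#' @export
total_minutes <- function(intervals) sum(intervals$end_s - intervals$start_s) / 60
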
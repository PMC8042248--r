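#' Match detected events against simulator ground truth
#'
#' Overlap-based matching on the same channel: a ground-truth ripple counts
#' as recovered if at least one accepted detection overlaps its time span,
#' and an accepted detection counts as true if it overlaps some
#' ground-truth ripple. Recall and precision are computed over accepted
#' detections and ground-truth rows of kind "ripple" only.
#'
#' @param detected `hfo_events` from [detect_hfo()].
#' @param truth ground-truth table from [inject_events()].
#' @return list with `recall`, `precision`, `n_truth`, `n_detected`,
#'   logical vectors `truth_hit` and `detected_true`.
#' @export
match_events <- function(detected, truth) {
  acc <- detected[detected$status == "accepted", , drop = FALSE]
  rip <- truth[truth$kind == "ripple", , drop = FALSE]
  overlaps <- function(ch, a0, a1) {
    any(acc$channel == ch & acc$onset_s < a1 & acc$offset_s > a0)
  }
  truth_hit <- vapply(seq_len(nrow(rip)), function(i)
    overlaps(rip$channel[i], rip$onset_s[i],
             rip$onset_s[i] + rip$duration_ms[i] / 1000), TRUE)
  detected_true <- vapply(seq_len(nrow(acc)), function(j)
    any(rip$channel == acc$channel[j] &
          rip$onset_s < acc$offset_s[j] &
          rip$onset_s + rip$duration_ms / 1000 > acc$onset_s[j]), TRUE)
  list(recall = if (nrow(rip)) mean(truth_hit) else NA_real_,
       precision = if (nrow(acc)) mean(detected_true) else NA_real_,
       n_truth = nrow(rip), n_detected = nrow(acc),
       truth_hit = truth_hit, detected_true = detected_true)
}
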
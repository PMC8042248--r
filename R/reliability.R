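#' Group 5-min intervals into test-retest blocks
#'
#' Consecutive, non-overlapping groups of `block_minutes / 5` intervals;
#' the trailing remainder is dropped. Ten-minute blocks require a total
#' recording duration strictly greater than 20 min (at least two full
#' blocks plus headroom, following the cohort eligibility rule); 5-min
#' blocks require at least two intervals.
#'
#' @param intervals data.frame from [select_intervals()].
#' @param block_minutes 5 or 10.
#' @return data.frame `block`, `start_s`, `end_s`, and a list-column
#'   `interval_index` of the member interval indices.
#' @export
make_blocks <- function(intervals, block_minutes = 10) {
  per <- block_minutes / 5
  if (per != round(per) || per < 1)
    stop("block_minutes must be a multiple of 5")
  tot_min <- total_minutes(intervals)
  if (block_minutes == 10 && tot_min <= 20)
    stop("eligibility error: 10-min reliability requires > 20 min of data")
  n_blocks <- floor(nrow(intervals) / per)
  if (n_blocks < 2)
    stop("eligibility error: fewer than 2 blocks")
  idx <- lapply(seq_len(n_blocks), function(b)
    intervals$index[((b - 1) * per + 1):(b * per)])
  data.frame(block = seq_len(n_blocks),
             start_s = vapply(seq_len(n_blocks), function(b)
               intervals$start_s[(b - 1) * per + 1], 0),
             end_s = vapply(seq_len(n_blocks), function(b)
               intervals$end_s[b * per], 0),
             interval_index = I(idx))
}

#' HFO area of one block
#'
#' The channel with the highest HFO rate among the accepted events of the
#' block (= highest count, since all channels share the block duration);
#' ties break by event count then lexicographic channel name. Blocks
#' without accepted events yield the none-sentinel `NA`.
#'
#' @param events `hfo_events`; rows are restricted to the block span.
#' @param block one row of [make_blocks()] output (or a list with
#'   `start_s`, `end_s`).
#' @return channel label or `NA_character_`.
#' @export
hfo_area <- function(events, block) {
  acc <- events[events$status == "accepted" &
                  events$onset_s < block$end_s &
                  events$offset_s > block$start_s, , drop = FALSE]
  if (!nrow(acc)) return(NA_character_)
  cnt <- sort(table(acc$channel), decreasing = TRUE)
  top <- names(cnt)[cnt == max(cnt)]
  sort(top)[1]
}

#' Test-retest reliability of the HFO spatial profile
#'
#' Percentage of unordered block pairs whose HFO areas agree; agreement
#' means an identical top channel, with the none-sentinel agreeing only
#' with none. Permutation-invariant in the block order, 100 for constant
#' profiles, 0 for pairwise-distinct ones.
#'
#' @param tops character vector of per-block HFO areas (NA = none), or
#'   alternatively pass `events` and `blocks` to compute them.
#' @param events,blocks optional: compute per-block areas first.
#' @return list with `reliability_pct`, `n_blocks`, `per_block_top`.
#' @export
test_retest_reliability <- function(tops = NULL, events = NULL,
                                    blocks = NULL) {
  if (is.null(tops)) {
    stopifnot(!is.null(events), !is.null(blocks))
    tops <- vapply(seq_len(nrow(blocks)), function(b)
      hfo_area(events, blocks[b, ]), "")
  }
  n <- length(tops)
  if (n < 2) stop("eligibility error: at least 2 blocks required")
  pairs <- utils::combn(n, 2)
  agree <- vapply(seq_len(ncol(pairs)), function(k) {
    a <- tops[pairs[1, k]]; b <- tops[pairs[2, k]]
    (is.na(a) && is.na(b)) || (!is.na(a) && !is.na(b) && a == b)
  }, TRUE)
  list(reliability_pct = 100 * mean(agree), n_blocks = n,
       per_block_top = tops)
}
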
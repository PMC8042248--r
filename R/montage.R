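#' The 19 montaged electrodes of the international 10-20 system
#'
#' A1 and A2 are recorded in 21-electrode setups but carry no neighbours in
#' the bipolar montage; the remaining 19 scalp electrodes generate the 52
#' bipolar derivations.
#' @return character vector of 19 electrode names.
#' @export
electrodes_1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

.montage_env <- new.env(parent = emptyenv())

#' Bipolar neighbour adjacency of the 10-20 system
#'
#' The published constraint is only that all combinations of neighbouring
#' electrodes over the 10-20 set yield 52 bipolar channels. The shipped
#' adjacency combines longitudinal, transverse and diagonal nearest
#' neighbours of the 19-electrode grid (plus the frontopolar/occipital
#' midline diagonals) and yields exactly 52 pairs; it contains every
#' derivation name that appears in published per-patient summaries
#' (e.g. "P3-O1", "T3-F3", "P4-Cz").
#'
#' @return data.frame with columns `name`, `anode`, `cathode`, `homologue`
#'   (the left-right mirror derivation; midline-only and cross-midline
#'   pairs map to themselves).
#' @export
bipolar_adjacency_1020 <- function() {
  if (is.null(.montage_env$adjacency)) {
    path <- system.file("extdata", "bipolar_adjacency_1020.tsv",
                        package = "scalpHFO", mustWork = TRUE)
    .montage_env$adjacency <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .montage_env$adjacency
}

#' Canonicalize a bipolar channel name
#'
#' Derivation names are accepted in either electrode order ("T3-F3" or
#' "F3-T3") and mapped to the order used by the shipped adjacency table.
#' @param name character vector of "A-B" names.
#' @return canonical names; NA for pairs not in the adjacency set.
#' @export
canonical_bipolar <- function(name) {
  adj <- bipolar_adjacency_1020()
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  parts <- strsplit(name, "-", fixed = TRUE)
  bad <- lengths(parts) != 2
  a <- vapply(parts, function(p) p[1], "")
  b <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")
  idx <- match(key(a, b), key(adj$anode, adj$cathode))
  out <- adj$name[idx]
  out[bad] <- NA_character_
  out
}

#' Homologous (mirror-hemisphere) derivation of a bipolar channel
#'
#' @param name bipolar channel name(s), any electrode order.
#' @return the left-right mirror derivation; `NA` when the pair has no
#'   distinct partner (midline-only pairs such as "Fz-Cz" and cross-midline
#'   pairs such as "Fp1-Fp2" self-map, i.e. they have no partner channel on
#'   which a bilateral co-occurrence could be observed).
#' @export
homologous_channel <- function(name) {
  adj <- bipolar_adjacency_1020()
  cn <- canonical_bipolar(name)
  hom <- adj$homologue[match(cn, adj$name)]
  hom[!is.na(hom) & hom == cn] <- NA_character_
  hom
}

#' Build the bipolar neighbour montage
#'
#' Re-references an electrode-space recording to the bipolar montage: every
#' adjacency pair whose two electrodes are present contributes a derived
#' channel anode - cathode (sample-wise difference). The full 19-electrode
#' 10-20 set yields exactly 52 bipolar channels; a subset of electrodes
#' yields the induced sub-montage.
#'
#' @param rec electrode-space `eeg_recording`.
#' @return bipolar-space `eeg_recording` with derivation labels.
#' @export
make_bipolar_montage <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$space != "electrode")
    stop("recording is already in bipolar space")
  adj <- bipolar_adjacency_1020()
  have <- rec$labels
  usable <- adj$anode %in% have & adj$cathode %in% have
  if (sum(usable) < 1 || length(intersect(have, electrodes_1020())) < 2)
    stop("montage error: fewer than 2 usable 10-20 electrodes")
  adj <- adj[usable, , drop = FALSE]
  der <- rec$samples[adj$anode, , drop = FALSE] -
    rec$samples[adj$cathode, , drop = FALSE]
  eeg_recording(der, rec$fs_hz, adj$name, annotations = rec$annotations,
                meta = rec$meta, space = "bipolar")
}

#' Drop channels before montage construction
#'
#' Removes electrodes with continuous interference (or any listed label)
#' from a recording; an empty list is the identity.
#' @param rec `eeg_recording`.
#' @param bad_labels character vector of labels to remove.
#' @return `eeg_recording` without the listed channels.
#' @export
exclude_channels <- function(rec, bad_labels) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad_labels) == 0) return(rec)
  keep <- !(rec$labels %in% bad_labels)
  eeg_recording(rec$samples[keep, , drop = FALSE], rec$fs_hz,
                rec$labels[keep], annotations = rec$annotations,
                meta = rec$meta, space = rec$space)
}
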
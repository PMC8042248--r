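# Minimal EDF (European Data Format, 16-bit) reader/writer: fixed 256-byte
# global header, 256 bytes per signal, then 1-s data records of little-endian
# int16 samples scaled between the physical and digital ranges.

pad_field <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Uses 1-second data records (so `fs_hz` must be a whole number) and a
#' per-channel symmetric physical range; the trailing partial second, if
#' any, is zero-padded. Annotations are not embedded; use the sidecar
#' events table written by [write_events_tsv()] / [simulate_dataset()].
#'
#' @param rec `eeg_recording` in microvolts.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  x <- rec$samples
  nch <- nrow(x)
  nrec <- ceiling(ncol(x) / fs)
  if (ncol(x) < nrec * fs)
    x <- cbind(x, matrix(0, nch, nrec * fs - ncol(x)))
  pmax_ <- apply(abs(x), 1, max)
  pmax_ <- ifelse(pmax_ > 0, pmax_ * 1.0001, 1)
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + nch), 8), pad_field("", 44),
    pad_field(nrec, 8), pad_field("1", 8), pad_field(nch, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    pad_field(rec$labels, 16), pad_field(rep("", nch), 80),
    pad_field(rep("uV", nch), 8),
    pad_field(sprintf("%.7g", -pmax_), 8), pad_field(sprintf("%.7g", pmax_), 8),
    pad_field(rep(dmin, nch), 8), pad_field(rep(dmax, nch), 8),
    pad_field(rep("", nch), 80), pad_field(rep(fs, nch), 8),
    pad_field(rep("", nch), 32))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  scale <- (dmax - dmin) / (2 * pmax_)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round((x[, idx, drop = FALSE] + pmax_) * scale + dmin)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) {
    raw <- readBin(con, "raw", n)
    trimws(rawToChar(raw))
  }
  version <- rd(8); patient <- rd(80); recording <- rd(80)
  startdate <- rd(8); starttime <- rd(8)
  nbytes <- as.integer(rd(8)); reserved <- rd(44)
  nrec <- as.integer(rd(8)); recdur <- as.numeric(rd(8)); nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1) stop("EDF parse error: bad channel count")
  per <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- per(16); transducer <- per(80); dim_ <- per(8)
  pmin_ <- as.numeric(per(8)); pmax_ <- as.numeric(per(8))
  dmin <- as.numeric(per(8)); dmax <- as.numeric(per(8))
  prefilter <- per(80); spr <- as.integer(per(8)); per(32)
  list(nrec = nrec, recdur = recdur, nch = nch, labels = labels,
       pmin = pmin_, pmax = pmax_, dmin = dmin, dmax = dmax, spr = spr)
}

#' Read an EDF file
#'
#' @param path EDF file (16-bit samples).
#' @return `eeg_recording` in electrode space with the file's labels
#'   normalized via [normalize_electrode_label()]; unmapped labels are kept
#'   verbatim.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (file.info(path)$size < 256) stop("EDF parse error: file too short")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  if (any(is.na(h$spr)) || any(h$spr <= 0) || is.na(h$recdur) || h$recdur <= 0)
    stop("EDF parse error: missing sampling information")
  fs <- h$spr / h$recdur
  if (length(unique(fs)) != 1)
    stop("EDF with heterogeneous sampling rates is not supported")
  fs <- fs[1]
  out <- matrix(0, h$nch, h$nrec * h$spr[1])
  gain <- (h$pmax - h$pmin) / (h$dmax - h$dmin)
  for (r in seq_len(h$nrec)) {
    raw <- readBin(con, "integer", n = h$nch * h$spr[1], size = 2,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = h$spr[1])
    idx <- ((r - 1) * h$spr[1] + 1):(r * h$spr[1])
    out[, idx] <- t((block - rep(h$dmin, each = h$spr[1])) *
                      rep(gain, each = h$spr[1]) +
                      rep(h$pmin, each = h$spr[1]))
  }
  labels <- normalize_electrode_label(h$labels)
  space <- if (all(grepl("-", labels))) "bipolar" else "electrode"
  eeg_recording(out, fs, labels, space = space)
}

#' Normalize electrode labels to canonical 10-20 names
#'
#' Strips "EEG " prefixes and reference suffixes ("-Ref", "-LE", "-A1",
#' "-A2"), fixes case, and maps modified combinatorial aliases (T7/T8/P7/P8)
#' to the classic T3/T4/T5/T6 names. Bipolar derivation names ("P3-O1")
#' pass through with each side normalized.
#'
#' @param labels character vector.
#' @return normalized labels; inputs that map to nothing are returned
#'   trimmed but otherwise verbatim.
#' @export
normalize_electrode_label <- function(labels) {
  canon <- c(electrodes_1020(), "A1", "A2")
  alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  norm1 <- function(s) {
    s <- trimws(s)
    s <- sub("^EEG[ _]+", "", s, ignore.case = TRUE)
    s <- sub("[-_ ](Ref|LE|A1|A2|M1|M2)$", "", s, ignore.case = TRUE)
    hit <- match(toupper(s), toupper(canon))
    if (!is.na(hit)) return(canon[hit])
    up <- toupper(s)
    if (up %in% names(alias)) return(alias[[up]])
    s
  }
  montaged <- electrodes_1020()
  vapply(labels, function(s) {
    s <- trimws(s)
    if (grepl("^[^-]+-[^-]+$", s)) {
      p <- strsplit(s, "-", fixed = TRUE)[[1]]
      a <- norm1(p[1]); b <- norm1(p[2])
      if (a %in% montaged && b %in% montaged) return(paste0(a, "-", b))
    }
    norm1(s)
  }, "", USE.NAMES = FALSE)
}

read_events_sidecar <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  lab <- if ("trial_type" %in% names(ev)) ev$trial_type else ev$label
  data.frame(onset_s = as.numeric(ev$onset),
             duration_s = as.numeric(ev$duration),
             label = as.character(lab), stringsAsFactors = FALSE)
}

#' Load a scalp EEG recording from disk
#'
#' `dialect = "edf"` reads a single EDF file; a BIDS-style sidecar
#' `<base>_events.tsv` (columns onset, duration, trial_type) next to the
#' file, or `<base sans _eeg>_events.tsv`, populates the annotations.
#' `dialect = "bids"` reads a directory containing one `*_eeg.edf` and its
#' `*_events.tsv`.
#'
#' @param path file (edf) or directory (bids).
#' @param dialect "edf" or "bids".
#' @return `eeg_recording`.
#' @export
load_recording <- function(path, dialect = c("edf", "bids")) {
  dialect <- match.arg(dialect)
  if (dialect == "bids") {
    if (!dir.exists(path)) stop("BIDS path must be a directory")
    edf <- list.files(path, "_eeg\\.edf$", full.names = TRUE,
                      recursive = TRUE)
    if (length(edf) == 0)
      edf <- list.files(path, "\\.edf$", full.names = TRUE, recursive = TRUE)
    if (length(edf) == 0) stop("no EDF file found under ", path)
    path <- edf[1]
  }
  rec <- read_edf(path)
  base <- sub("\\.edf$", "", path, ignore.case = TRUE)
  cand <- c(paste0(sub("_eeg$", "", base), "_events.tsv"),
            paste0(base, "_events.tsv"))
  side <- cand[file.exists(cand)]
  if (length(side)) rec$annotations <- read_events_sidecar(side[1])
  rec
}

#' Write a detected-event table to a BIDS-events-like TSV
#'
#' @param events `hfo_events` data.frame (see [detect_hfo()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(events, path) {
  cols <- intersect(c("channel", "onset_s", "duration_ms", "frequency_hz",
                      "amplitude_uv", "snr", "status"), names(events))
  utils::write.table(events[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
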
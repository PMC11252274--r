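# Minimal EDF (16-bit European Data Format) writer/reader for the simulated
# sessions, plus the events TSV sidecar. One data record per second; NaN
# samples are stored as the reserved digital value -32768 and restored on
# read. Physical scaling uses the header strings as written, so a
# write/read round trip is exact up to 16-bit quantization.

pad_str <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

#' Write a recording as EDF
#'
#' @param rec a `raw_recording` (microvolt signal).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  sig <- rec$signal
  ns <- nrow(sig)
  fs <- rec$fs_hz
  n_true <- ncol(sig)
  n_rec <- ceiling(n_true / fs)
  if (n_rec * fs > n_true) sig <- cbind(sig, matrix(0, ns, n_rec * fs - n_true))

  fin <- sig[is.finite(sig)]
  rng <- if (length(fin)) max(1, max(abs(fin))) else 1
  pmin_s <- formatC(-rng, format = "g", digits = 6)
  pmax_s <- formatC(rng, format = "g", digits = 6)
  pmin_v <- as.numeric(pmin_s); pmax_v <- as.numeric(pmax_s)
  dmin <- -32767; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_str("0", 8), pad_str(rec$session_id, 80), pad_str("vepdecode synthetic", 80),
    pad_str("01.01.26", 8), pad_str("00.00.00", 8),
    pad_str(256 * (1 + ns), 8), pad_str(sprintf("NSAMP=%d", n_true), 44),
    pad_str(n_rec, 8), pad_str(1, 8), pad_str(ns, 4)
  )
  sh <- function(f) paste0(vapply(seq_len(ns), f, ""), collapse = "")
  hdr <- paste0(hdr,
    sh(function(i) pad_str(rec$layout$names[i], 16)),
    sh(function(i) pad_str("synthetic", 80)),
    sh(function(i) pad_str("uV", 8)),
    sh(function(i) pad_str(pmin_s, 8)),
    sh(function(i) pad_str(pmax_s, 8)),
    sh(function(i) pad_str(dmin, 8)),
    sh(function(i) pad_str(dmax, 8)),
    sh(function(i) pad_str("none", 80)),
    sh(function(i) pad_str(fs, 8)),
    sh(function(i) pad_str("", 32)))
  writeChar(hdr, con, eos = NULL)

  scale <- (dmax - dmin) / (pmax_v - pmin_v)
  dig <- round((sig - pmin_v) * scale) + dmin
  dig[!is.finite(sig)] <- -32768
  dig <- pmin(pmax(dig, -32768), 32767)
  # interleave per record: record-major, signal within record
  arr <- array(dig, dim = c(ns, fs, n_rec))        # channel x sample x record
  out <- aperm(arr, c(2, 1, 3))                    # sample x channel x record
  writeBin(as.integer(out), con, size = 2, endian = "little")
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return a `raw_recording` without events (attach via [read_session()]).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); session_id <- rd(80); rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8)); rd(8); ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_v <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_v <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  abort_if(length(unique(spr)) != 1L, "unequal per-signal sampling rates unsupported")
  fs <- spr[1]
  dig <- readBin(con, integer(), n = ns * fs * n_rec, size = 2, endian = "little", signed = TRUE)
  arr <- array(dig, dim = c(fs, ns, n_rec))
  sig <- matrix(aperm(arr, c(2, 1, 3)), nrow = ns)
  nan_mask <- sig == -32768
  out <- sweep(sweep(sig - dmin[1], 1, (dmax[1] - dmin[1]) / (pmax_v - pmin_v), "/"), 1, pmin_v, "+")
  out[nan_mask] <- NaN
  n_true <- if (grepl("NSAMP=", reserved)) as.integer(sub("NSAMP=", "", reserved)) else ncol(out)
  out <- out[, seq_len(n_true), drop = FALSE]
  structure(list(signal = out, fs_hz = fs, layout = channel_layout(labels),
                 events = NULL, session_id = session_id),
            class = "raw_recording")
}

#' Write the events sidecar TSV
#' @param events an `event_list`.
#' @param path output TSV path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an events sidecar TSV
#' @param path TSV path.
#' @param fs_hz sampling rate used to rebuild the session geometry.
#' @return an `event_list` with a reconstructed `session_spec` attribute.
#' @export
read_events_tsv <- function(path, fs_hz = 250L) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE)
  n_classes <- max(ev$class_id) + 1L
  images_per_class <- nrow(ev) / n_classes
  step_s <- if (nrow(ev) > 1) diff(ev$onset_s[1:2]) else ev$duration_s[1] + 1
  spec <- session_spec(n_classes, images_per_class,
                       stim_dur_s = ev$duration_s[1],
                       isi_s = step_s - ev$duration_s[1], fs_hz = fs_hz)
  class(ev) <- c("event_list", "data.frame")
  attr(ev, "spec") <- spec
  ev
}

#' Persist a session (EDF + events TSV)
#' @param rec a `raw_recording` with events attached.
#' @param dir output directory.
#' @return named paths, invisibly.
#' @export
write_session <- function(rec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edf <- file.path(dir, paste0(rec$session_id, ".edf"))
  tsv <- file.path(dir, paste0(rec$session_id, "_events.tsv"))
  write_edf(rec, edf)
  write_events_tsv(rec$events, tsv)
  invisible(c(edf = edf, events = tsv))
}

#' Load a session (EDF + events TSV)
#' @param edf_path EDF file.
#' @param events_path events TSV; defaults to the sibling `*_events.tsv`.
#' @return a `raw_recording` with events attached.
#' @export
read_session <- function(edf_path, events_path = NULL) {
  if (is.null(events_path)) {
    events_path <- sub("\\.edf$", "_events.tsv", edf_path)
  }
  rec <- read_edf(edf_path)
  rec$events <- read_events_tsv(events_path, fs_hz = rec$fs_hz)
  rec
}
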
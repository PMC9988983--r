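#' Write a recording to an EDF file
#'
#' Minimal European Data Format writer: one data record per second,
#' electrode labels as channel names, signals quantized to 16-bit integers
#' over their physical range. Sufficient for round-tripping synthetic
#' cohorts through standard PSG tooling.
#'
#' @param recording a [psg_recording()].
#' @param path output file path.
#' @export
write_edf <- function(recording, path) {
  sig <- recording$signals
  fs <- recording$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(sig)
  nrec <- floor(ncol(sig) / fs)
  sig <- sig[, seq_len(nrec * fs), drop = FALSE]
  pmin_ <- apply(sig, 1, min); pmax_ <- apply(sig, 1, max)
  pmax_[pmax_ <= pmin_] <- pmin_[pmax_ <= pmin_] + 1
  pad <- function(x, w) {
    x <- substr(as.character(x), 1, w)
    formatC(x, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad(recording$subject_id, 80), pad(recording$recording_id, 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 + ns * 256, 8), pad("", 44), pad(nrec, 8), pad(1, 8), pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fld <- function(vals, w) writeChar(paste0(vapply(vals, pad, "", w),
                                            collapse = ""), con, eos = NULL)
  fld(recording$electrodes, 16)
  fld(rep("synthetic PSG", ns), 80)
  fld(rep("uV", ns), 8)
  fld(formatC(pmin_, digits = 6, format = "g"), 8)
  fld(formatC(pmax_, digits = 6, format = "g"), 8)
  fld(rep(-32768, ns), 8)
  fld(rep(32767, ns), 8)
  fld(rep("none", ns), 80)
  fld(rep(fs, ns), 8)
  fld(rep("", ns), 32)
  scale <- 65535 / (pmax_ - pmin_)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((sig[ch, idx] - pmin_[ch]) * scale[ch] - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return list with `signals` (channel x sample matrix with electrode row
#'   names) and `fs`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8)); rd(8)
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  out <- matrix(0, ns, nrec * spr[1], dimnames = list(labels, NULL))
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      phys <- pmin_[ch] + (dig - dmin[ch]) *
        (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
      out[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  list(signals = out, fs = spr[1])
}

#' Hypnogram CSV round trip
#'
#' Two-column CSV (`epoch_index`, `label`) with labels in
#' W, N1, N2, N3, REM, MASK; epoch indices are zero-based.
#'
#' @param hypnogram a [stage_sequence()].
#' @param path CSV path.
#' @export
write_hypnogram_csv <- function(hypnogram, path) {
  labs <- unclass(hypnogram)
  utils::write.csv(data.frame(epoch_index = seq_along(labs) - 1L,
                              label = stage_label(labs)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @export
read_hypnogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  harmonize_stages(df$label[order(df$epoch_index)], scheme = "AASM")
}

#' Compact single-file recording container
#'
#' Serializes a recording (signals, labels and metadata) to the package's
#' native RDS container for fast loading in pipelines and tests.
#' @param recording a [psg_recording()].
#' @param path file path.
#' @export
write_psg_container <- function(recording, path) {
  saveRDS(recording, path)
  invisible(path)
}

#' @rdname write_psg_container
#' @export
read_psg_container <- function(path) {
  rec <- readRDS(path)
  stopifnot(inherits(rec, "psg_recording"))
  rec
}
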
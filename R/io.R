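# Recording I/O: delimited text matrix + JSON sidecar (read/write) and a
# minimal EDF (European Data Format) reader/writer (16-bit, one data record).

sidecar_path <- function(path) paste0(path, ".json")

#' Read a multichannel recording
#'
#' Delimited files are channels x samples numeric matrices (TSV) and must be
#' accompanied by a JSON sidecar `<file>.json` with `channel_labels`,
#' `sampling_rate` and optionally `subject_id` and `label`.  EDF files are
#' self-describing.
#'
#' @param path file path.
#' @param format `"delimited"` or `"edf"`.
#' @return a `recording`.
#' @export
read_recording <- function(path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  if (format == "edf") return(read_edf(path))
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop_input(sprintf("missing sidecar file: expected %s", sc))
  meta <- jsonlite::fromJSON(sc)
  if (is.null(meta$sampling_rate) || meta$sampling_rate <= 0)
    stop_input("sidecar must provide sampling_rate > 0")
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE),
    error = function(e) stop_input(sprintf("parse error in %s: %s", path,
                                           conditionMessage(e))))
  m <- as.matrix(dt)
  if (!is.numeric(m)) stop_input(sprintf("non-numeric values in %s", path))
  if (nrow(m) != length(meta$channel_labels))
    stop_input(sprintf("%s: %d rows but %d channel labels in sidecar",
                       path, nrow(m), length(meta$channel_labels)))
  dimnames(m) <- NULL
  new_recording(subject_id = meta$subject_id %||% basename(path),
                label = if (is.null(meta$label)) NA_integer_ else as.integer(meta$label),
                channel_labels = meta$channel_labels,
                sampling_rate = meta$sampling_rate, data = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording
#'
#' @param rec a `recording`.
#' @param path output path.
#' @param format `"delimited"` (TSV + JSON sidecar) or `"edf"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "recording"))
  if (format == "edf") return(write_edf(rec, path))
  data.table::fwrite(data.table::as.data.table(rec$data), path, sep = "\t",
                     col.names = FALSE)
  jsonlite::write_json(list(subject_id = rec$subject_id, label = rec$label,
                            channel_labels = rec$channel_labels,
                            sampling_rate = rec$sampling_rate),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- minimal EDF ------------------------------------------------------------

pad_field <- function(x, width) {
  s <- substr(format(x), 1, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  ns <- ncol(rec$data); nch <- nrow(rec$data)
  duration <- ns / rec$sampling_rate
  pmin_ <- apply(rec$data, 1, min); pmax_ <- apply(rec$data, 1, max)
  pad <- pmax((pmax_ - pmin_) * 0.001, 1e-6)
  pmin_ <- pmin_ - pad; pmax_ <- pmax_ + pad
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(rec$subject_id, 80), pad_field("eegtopoclass", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 + 256 * nch, 8), pad_field("", 44),
    pad_field(1, 8), pad_field(format(duration, digits = 7), 8), pad_field(nch, 4))
  writeChar(hdr, con, eos = NULL)
  f <- function(vals, w) writeChar(paste0(vapply(vals, pad_field, "", w), collapse = ""),
                                   con, eos = NULL)
  f(rec$channel_labels, 16); f(rep("", nch), 80); f(rep("uV", nch), 8)
  f(formatC(pmin_, digits = 6, format = "g"), 8)
  f(formatC(pmax_, digits = 6, format = "g"), 8)
  f(rep(-32768, nch), 8); f(rep(32767, nch), 8); f(rep("", nch), 80)
  f(rep(ns, nch), 8); f(rep("", nch), 32)
  for (ch in seq_len(nch)) {
    dig <- round((rec$data[ch, ] - pmin_[ch]) / (pmax_[ch] - pmin_[ch]) * 65535 - 32768)
    writeBin(as.integer(pmin(32767, pmax(-32768, dig))), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                      # version
  subject_id <- rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  duration <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (!isTRUE(nch > 0)) stop_input(sprintf("malformed EDF header in %s", path))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  data <- matrix(0, nch, spr[1] * nrec)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      phys <- (dig - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch]) + pmin_[ch]
      data[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  new_recording(subject_id = subject_id, channel_labels = labels,
                sampling_rate = spr[1] / duration, data = data)
}
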
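#' Write segments to delimited text with a JSON manifest
#'
#' Each single-channel segment becomes one plain-text file (comment
#' header with sampling rate, label and identifiers; one sample per
#' line). A `manifest.json` in the same directory lists every file with
#' its metadata, and is what [read_segments()] consumes.
#'
#' @param segments list of [eeg_epoch()] objects (single-channel).
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest path.
#' @export
write_segments <- function(segments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    seg <- segments[[i]]
    fn <- sprintf("segment_%04d.txt", i)
    path <- file.path(dir, fn)
    con <- file(path, "w")
    writeLines(c(sprintf("# fs: %g", seg$fs),
                 sprintf("# label: %s", seg$label),
                 sprintf("# subject: %s", seg$subject_id),
                 sprintf("# channel: %s", seg$channel_names[1])), con)
    writeLines(format(as.vector(seg$data[1, ]), digits = 17, trim = TRUE,
                      scientific = FALSE), con)
    close(con)
    entries[[i]] <- list(file = fn, fs = seg$fs, label = seg$label,
                         subject = seg$subject_id,
                         channel = seg$channel_names[1])
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(segments = entries), manifest,
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read labeled EEG segments from disk
#'
#' @param path for `format = "delimited"`: a directory containing
#'   `manifest.json` (as written by [write_segments()]) or the manifest
#'   file itself; for `format = "edf"`: one or more EDF file paths.
#' @param format `"delimited"` or `"edf"`.
#' @return list of [eeg_epoch()] objects. All segments must share one
#'   sampling rate.
#' @export
read_segments <- function(path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  segments <- if (format == "edf") {
    unlist(lapply(path, function(p) {
      ep <- read_edf(p)
      lapply(seq_len(nrow(ep$data)), function(ch)
        eeg_epoch(ep$data[ch, , drop = FALSE], ep$fs, ep$label,
                  subject_id = ep$subject_id,
                  channel_names = ep$channel_names[ch]))
    }), recursive = FALSE)
  } else {
    manifest <- if (dir.exists(path)) file.path(path, "manifest.json") else path
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    info <- jsonlite::read_json(manifest, simplifyVector = FALSE)
    lapply(info$segments, function(e) {
      for (fld in c("file", "fs", "label"))
        if (is.null(e[[fld]]))
          stop(sprintf("manifest entry missing '%s' (file: %s)", fld,
                       e$file %||% "?"))
      f <- file.path(dirname(manifest), e$file)
      if (!file.exists(f)) stop("segment file not found: ", f)
      lines <- readLines(f)
      x <- as.numeric(lines[!startsWith(lines, "#")])
      eeg_epoch(matrix(x, nrow = 1), e$fs, e$label,
                subject_id = e$subject %||% "S?",
                channel_names = e$channel %||% "ch1")
    })
  }
  fss <- unique(vapply(segments, function(s) s$fs, numeric(1)))
  if (length(fss) > 1)
    stop("segments disagree on sampling rate: ", paste(fss, collapse = ", "))
  segments
}

# ---- minimal European Data Format (EDF) support -------------------------
# Fixed-width ASCII header (256 bytes + 256 per signal) followed by
# 16-bit little-endian samples. One data record spanning the whole epoch
# is written; reading handles any record count.

pad <- function(s, width) formatC(as.character(s), width = -width)

# Numeric rendering that always fits an 8-character EDF header field.
num8 <- function(v) {
  s <- formatC(v, format = "g", digits = 6)
  if (nchar(s) > 8) s <- formatC(v, format = "e", digits = 1)
  s
}

#' Write an epoch to an EDF file
#'
#' Minimal single-record EDF writer used for interchange and round-trip
#' testing. The class label and subject are stored in the recording-id
#' header field so [read_edf()] can recover them.
#'
#' @param epoch an [eeg_epoch()] (any channel count).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_edf <- function(epoch, path) {
  d <- epoch$data
  ns <- nrow(d)
  n <- ncol(d)
  dur <- n / epoch$fs
  pmaxs <- apply(abs(d), 1, max)
  pmaxs[pmaxs == 0] <- 1
  # round the physical range through its 8-char header rendering so the
  # writer and reader use bit-identical scale factors
  pmaxs <- vapply(pmaxs * 1.0001, function(v) as.numeric(num8(v)), 0)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad("0", 8), pad(epoch$subject_id, 80),
                pad(sprintf("label=%s subject=%s", epoch$label,
                            epoch$subject_id), 80),
                pad("01.01.20", 8), pad("00.00.00", 8),
                pad(256 * (1 + ns), 8), pad("", 44), pad(1, 8),
                pad(num8(dur), 8), pad(ns, 4))
  sig_hdr <- paste0(
    paste(vapply(epoch$channel_names, pad, "", width = 16), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad("uV", 8), ns), collapse = ""),
    paste(vapply(-pmaxs, function(v) pad(num8(v), 8), ""), collapse = ""),
    paste(vapply(pmaxs, function(v) pad(num8(v), 8), ""), collapse = ""),
    paste(rep(pad(-32768, 8), ns), collapse = ""),
    paste(rep(pad(32767, 8), ns), collapse = ""),
    paste(rep(pad("", 80), ns), collapse = ""),
    paste(rep(pad(n, 8), ns), collapse = ""),
    paste(rep(pad("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)
  for (ch in seq_len(ns)) {
    dig <- round((d[ch, ] + pmaxs[ch]) / (2 * pmaxs[ch]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG epoch
#'
#' @param path an EDF file.
#' @param label class label override; when `NULL` the label is parsed
#'   from the recording-id header field (falling back to
#'   `"pre_seizure"`).
#' @return an [eeg_epoch()].
#' @export
read_edf <- function(path, label = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) {
    raw <- readBin(con, "raw", nchars)
    trimws(rawToChar(raw))
  }
  rd(8)                                  # version
  subject <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)            # dates, header bytes, reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  chn <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)          # prefiltering
  nr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)          # reserved
  data <- matrix(0, ns, nr[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", nr[ch], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin_[ch]) * (pmax_[ch] - pmin_[ch]) /
        (dmax_[ch] - dmin_[ch]) + pmin_[ch]
      data[ch, ((r - 1) * nr[ch] + 1):(r * nr[ch])] <- phys
    }
  }
  fs <- nr[1] / rec_dur
  if (is.null(label)) {
    m <- regmatches(rec_id, regexpr("label=[a-z_]+", rec_id))
    label <- if (length(m)) sub("label=", "", m) else "pre_seizure"
  }
  eeg_epoch(data, fs, label, subject_id = subject, channel_names = chn)
}
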
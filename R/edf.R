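# Minimal EDF (European Data Format, 16-bit) reader and writer. Only the
# plain continuous-EDF subset needed here: one fixed-rate record layout,
# all channels at the same sampling rate. No EDF package exists in the
# dependency set, so the format is handled directly; the format is an
# ASCII header plus little-endian int16 data records.

.edf_pad <- function(x, width) formatC(as.character(x), width = width,
                                       flag = "-")

# shortest "g" representation of a physical bound that fits the 8-char field
.edf_num <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    s
  }, "")
}

#' Write a recording to an EDF file
#'
#' One data record per second, all channels at `rec$fs` samples per record.
#' Physical scaling spans the observed per-channel range mapped onto the
#' full 16-bit digital range, so the round-trip error is bounded by the
#' quantization step.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  ns <- nrow(rec$data)
  spr <- as.integer(rec$fs)             # samples per 1 s record
  if (abs(rec$fs - spr) > 1e-9)
    stop_compen("EDF writer requires an integer sampling rate")
  n_rec <- ncol(rec$data) %/% spr
  if (n_rec * spr != ncol(rec$data))
    stop_compen("EDF writer requires a whole number of 1 s records")
  pmin_ <- apply(rec$data, 1, min)
  pmax_ <- apply(rec$data, 1, max)
  same <- pmax_ - pmin_ < 1e-12
  pmax_[same] <- pmin_[same] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(paste0(.edf_pad(x, width),
                                            collapse = ""), con,
                                     eos = NULL)
  # fixed header (256 bytes)
  wr("0", 8)                                    # version
  wr(substr(paste0(rec$subject_id, " ", rec$gender), 1, 80), 80)
  wr(substr(paste0("emotion: ", rec$emotion), 1, 80), 80)
  wr("01.01.00", 8); wr("00.00.00", 8)          # date, time
  wr(256 + ns * 256, 8)                         # header bytes
  wr("", 44)
  wr(n_rec, 8); wr(1, 8)                        # records, duration (s)
  wr(ns, 4)
  # signal headers (ns * 256 bytes)
  wr(substr(rec$channel_labels, 1, 16), 16)
  wr(rep("", ns), 80)                           # transducer
  wr(rep("uV", ns), 8)
  wr(.edf_num(pmin_), 8)
  wr(.edf_num(pmax_), 8)
  wr(rep(-32768, ns), 8); wr(rep(32767, ns), 8)
  wr(rep("", ns), 80)                           # prefiltering
  wr(rep(spr, ns), 8)
  wr(rep("", ns), 32)
  # data records
  pmin_r <- as.numeric(.edf_num(pmin_))
  pmax_r <- as.numeric(.edf_num(pmax_))
  scale <- (32767 - (-32768)) / (pmax_r - pmin_r)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((rec$data[ch, cols] - pmin_r[ch]) * scale[ch] - 32768)
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Minimal continuous-EDF reader (16-bit samples, equal sampling rate on
#' all channels). Subject metadata is parsed from the patient field if it
#' was written by [write_edf()]; otherwise placeholders are used.
#'
#' @param path EDF file path.
#' @return A [recording()].
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_compen("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rdn <- function(width) as.numeric(rd(width))
  rd(8)                                  # version
  patient <- rd(80)
  rec_field <- rd(80)
  rd(8); rd(8)
  rdn(8)                                 # header bytes
  rd(44)
  n_rec <- rdn(8)
  dur <- rdn(8)
  ns <- as.integer(rdn(4))
  rds <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rds(16)
  rds(80); rds(8)
  pmin_ <- as.numeric(rds(8)); pmax_ <- as.numeric(rds(8))
  dmin_ <- as.numeric(rds(8)); dmax_ <- as.numeric(rds(8))
  rds(80)
  spr <- as.integer(as.numeric(rds(8)))
  rds(32)
  if (length(unique(spr)) != 1L)
    stop_compen("reader supports equal sampling rates on all channels only")
  fs <- spr[1] / dur
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * spr[1] + 1):(r * spr[1])
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      data[ch, cols] <- pmin_[ch] +
        (dig - dmin_[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax_[ch] - dmin_[ch])
    }
  }
  parts <- strsplit(patient, " +")[[1]]
  gender <- if (length(parts) >= 2 && parts[2] %in% c("female", "male"))
    parts[2] else "female"
  emotion <- sub("^emotion: *", "", rec_field)
  recording(parts[1] %||% "unknown", gender,
            if (nzchar(emotion)) emotion else "unknown",
            data, fs, labels)
}

#' Read a recording from CSV or EDF
#'
#' The CSV dialect is the one [write_recording()] produces (first column
#' time in seconds, one column per channel, JSON sidecar with metadata).
#'
#' @param path File path.
#' @param format `"csv"` or `"edf"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path))
  if (!file.exists(path)) stop_compen("file not found: ", path)
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time")
    stop_compen("CSV must start with a 'time' column")
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop_compen("sidecar manifest not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  missing <- setdiff(meta$channel_labels, names(df))
  if (length(missing))
    stop_compen("missing channel column(s): ", paste(missing, collapse = ", "))
  data <- t(as.matrix(df[, meta$channel_labels, drop = FALSE]))
  recording(meta$subject_id, meta$gender, meta$emotion, data, meta$fs,
            meta$channel_labels)
}
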
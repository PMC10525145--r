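CONTAINER_SCHEMA <- "erpfuse-epochs-1"

#' Write an epoched recording to the HDF5 epoch container
#'
#' Layout: datasets `/data` (trials x channels x time, microvolts),
#' `/labels`, `/channel_names`; root attributes `srate`, `window`,
#' `participant_id`, `schema_version`.
#'
#' @param rec an [epoched_recording].
#' @param path output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_container <- function(rec, path) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rec$data, path, "data")
  rhdf5::h5write(rec$labels, path, "labels")
  rhdf5::h5write(rec$channel_names, path, "channel_names")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(rec$srate, fid, "srate")
  rhdf5::h5writeAttribute(rec$window, fid, "window")
  rhdf5::h5writeAttribute(rec$participant_id, fid, "participant_id")
  rhdf5::h5writeAttribute(CONTAINER_SCHEMA, fid, "schema_version")
  invisible(path)
}

#' Read an epoched recording from the HDF5 epoch container
#'
#' @param path file written by [write_container()].
#' @return an [epoched_recording]; `read_container(write_container(rec))`
#'   reproduces `rec` exactly.
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  att <- rhdf5::h5readAttributes(path, "/")
  sv <- as.character(att$schema_version %||% "")
  if (!identical(sv, CONTAINER_SCHEMA))
    stop(sprintf("schema error: unrecognized schema_version '%s' (expected '%s')",
                 sv, CONTAINER_SCHEMA))
  ls <- rhdf5::h5ls(path)$name
  for (ds in c("data", "labels", "channel_names"))
    if (!ds %in% ls)
      stop(sprintf("schema error: container is missing the '%s' dataset", ds))
  epoched_recording(
    data = rhdf5::h5read(path, "data"),
    srate = as.numeric(att$srate),
    window = as.numeric(att$window),
    labels = as.character(rhdf5::h5read(path, "labels")),
    channel_names = as.character(rhdf5::h5read(path, "channel_names")),
    participant_id = as.character(att$participant_id))
}

#' Read an events table (TSV with header `onset_sample<TAB>label`)
#'
#' @param path TSV path.
#' @param vocabulary allowed labels.
#' @return data frame with integer `onset_sample` (1-based, strictly
#'   increasing) and character `label`.
#' @export
read_events <- function(path, vocabulary = c("rare", "frequent")) {
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!identical(names(ev)[1:2], c("onset_sample", "label")))
    stop("events file must have header 'onset_sample<TAB>label'")
  ev$onset_sample <- as.integer(ev$onset_sample)
  if (any(is.na(ev$onset_sample)) || any(ev$onset_sample < 1))
    stop("format error in field 'onset_sample': must be positive integers")
  if (any(diff(ev$onset_sample) <= 0))
    stop("format error in field 'onset_sample': must be strictly increasing")
  if (!all(ev$label %in% vocabulary))
    stop("format error in field 'label': unknown condition tag(s): ",
         paste(setdiff(ev$label, vocabulary), collapse = ", "))
  ev[, c("onset_sample", "label")]
}

edf_field <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

#' Read a continuous multichannel recording from an EDF file
#'
#' Minimal European Data Format reader: parses the fixed 256-byte header and
#' per-signal headers, reads the 16-bit data records, and applies the
#' digital-to-physical calibration. All signals must share one sampling rate.
#' Voltages are returned in microvolts (the `mV`/`V` physical-dimension
#' fields are converted).
#'
#' @param path EDF file.
#' @return list with `signal` (channels x samples matrix, microvolts),
#'   `srate` (Hz) and `channel_names`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  edf_field(con, 8)                              # version
  edf_field(con, 80); edf_field(con, 80)         # patient, recording
  edf_field(con, 8); edf_field(con, 8)           # start date, time
  header_bytes <- as.integer(edf_field(con, 8))
  edf_field(con, 44)                             # reserved
  n_records <- as.integer(edf_field(con, 8))
  rec_dur <- as.numeric(edf_field(con, 8))
  ns <- as.integer(edf_field(con, 4))
  if (is.na(ns) || ns < 1) stop("format error in field 'number of signals'")
  rd <- function(w) vapply(seq_len(ns), function(i) edf_field(con, w), "")
  labels <- rd(16); rd(80)
  phys_dim <- rd(8)
  phys_min <- as.numeric(rd(8)); phys_max <- as.numeric(rd(8))
  dig_min <- as.numeric(rd(8)); dig_max <- as.numeric(rd(8))
  rd(80)
  spr <- as.integer(rd(8)); rd(32)
  if (any(is.na(c(phys_min, phys_max, dig_min, dig_max, spr))))
    stop("format error in a per-signal calibration field")
  if (length(unique(spr)) != 1L)
    stop("format error in field 'samples per record': channels have mismatched lengths")
  if (header_bytes != 256L + 256L * ns)
    stop("format error in field 'header bytes'")
  if (is.na(n_records) || n_records < 1)
    stop("format error in field 'number of records'")
  srate <- spr[1] / rec_dur
  raw16 <- readBin(con, "integer", n = n_records * sum(spr), size = 2,
                   signed = TRUE, endian = "little")
  if (length(raw16) < n_records * sum(spr))
    stop("format error: data section shorter than the header declares")
  sig <- matrix(0, nrow = ns, ncol = n_records * spr[1])
  pos <- 0L
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      sig[s, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <-
        raw16[(pos + 1L):(pos + spr[s])]
      pos <- pos + spr[s]
    }
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  unit <- vapply(tolower(phys_dim), function(u)
    switch(u, "uv" = 1, "µv" = 1, "mv" = 1e3, "v" = 1e6, 1), 1.0)
  for (s in seq_len(ns))
    sig[s, ] <- ((sig[s, ] - dig_min[s]) * gain[s] + phys_min[s]) * unit[s]
  list(signal = sig, srate = srate, channel_names = labels)
}

pad_field <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n)
}

#' Write a continuous recording as a minimal EDF file
#'
#' Companion to [read_edf()], intended for producing small test inputs and
#' for exporting simulated continuous data. Uses 1-second data records; the
#' signal is truncated to a whole number of records.
#'
#' @param signal channels x samples matrix, microvolts.
#' @param srate sampling rate, Hz (integer samples per 1-s record).
#' @param path output path.
#' @param channel_names electrode labels.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, srate, path, channel_names = NULL) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1)
  ns <- nrow(signal)
  if (is.null(channel_names)) channel_names <- sprintf("ch%02d", seq_len(ns))
  spr <- as.integer(round(srate))
  n_records <- floor(ncol(signal) / spr)
  if (n_records < 1) stop("signal shorter than one 1-s data record")
  signal <- signal[, seq_len(n_records * spr), drop = FALSE]
  pmax_ <- max(1, ceiling(max(abs(signal))))
  dig_min <- -32768; dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, n) writeBin(charToRaw(pad_field(x, n)), con)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8); wr("", 44)
  wr(n_records, 8); wr("1", 8); wr(ns, 4)
  for (nm in channel_names) wr(nm, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(-pmax_, 8)
  for (i in seq_len(ns)) wr(pmax_, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  scale <- (dig_max - dig_min) / (2 * pmax_)
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (s in seq_len(ns)) {
      dig <- as.integer(round((signal[s, idx] + pmax_) * scale + dig_min))
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}
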
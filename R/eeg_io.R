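# Reading and writing multichannel EEG recordings (EDF and delimited text),
# selection of the 19-electrode 10-20 montage from a dense sensor net, and
# fixed-length analysis segment selection.

#' Construct an EEG recording
#'
#' @param data Channels x samples numeric matrix (microvolts).
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param participant_id Participant identifier.
#' @param age_code Integer age label of the recording (1 = infancy, 3, 5 or 7
#'   years in the cohort design; any integer accepted).
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels,
                          participant_id = "unknown", age_code = NA_integer_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("eeg_recording: data must be numeric")
  if (anyNA(data) || any(!is.finite(data))) {
    stop("eeg_recording: data contains NA or non-finite samples")
  }
  if (nrow(data) != length(channel_labels)) {
    stop("eeg_recording: ", nrow(data), " data rows but ",
         length(channel_labels), " channel labels")
  }
  if (!is.numeric(fs) || fs <= 0) stop("eeg_recording: fs must be positive")
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 participant_id = as.character(participant_id),
                 age_code = as.integer(age_code)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording '%s': %d channels x %d samples at %g Hz (%.1f s)",
              x$participant_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs))
  if (!is.na(x$age_code)) cat(sprintf(", age code %d", x$age_code))
  cat("\n")
  invisible(x)
}

#' HydroCel-style dense-net channel labels
#'
#' Labels of a 128-electrode geodesic sensor net: `E1`..`E128` plus the
#' vertex reference `Cz`.
#'
#' @return Character vector of length 129.
#' @export
hydrocel_labels <- function() {
  c(paste0("E", 1:128), "Cz")
}

# ---- delimited text I/O -----------------------------------------------------

write_recording_text <- function(rec, path) {
  df <- as.data.frame(t(rec$data))
  names(df) <- rec$channel_labels
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(fs = rec$fs, participant_id = rec$participant_id,
               age_code = rec$age_code)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

read_recording_text <- function(path, fs = NULL, participant_id = NULL,
                                age_code = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  fs <- fs %||% meta$fs
  if (is.null(fs)) {
    stop("read_recording: sampling rate not found; supply fs= or a '",
         basename(sidecar), "' sidecar")
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  mat <- suppressWarnings(vapply(raw, as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, names(raw)))
  bad <- which(is.na(mat), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("read_recording: non-numeric cell at row ", bad[1, 1],
         ", column '", colnames(mat)[bad[1, 2]], "' of ", path)
  }
  eeg_recording(t(mat), fs = as.numeric(fs),
                channel_labels = colnames(mat),
                participant_id = participant_id %||% meta$participant_id %||%
                  "unknown",
                age_code = age_code %||% meta$age_code %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal EDF I/O --------------------------------------------------------
# Plain EDF: 256-byte fixed header + 256 bytes per signal, then 16-bit
# little-endian samples. One data record holding the whole recording is
# written. Physical min/max are rounded outward to 6 significant digits so
# the 8-character ASCII header fields represent them exactly; samples are
# therefore recovered to within one digital quantum, (pmax - pmin) / 65535.

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = -width, flag = "-")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 6, width = -1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  edf_pad(s, width)
}

write_recording_edf <- function(rec, path) {
  nchan <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  pmin <- apply(rec$data, 1, min)
  pmax <- apply(rec$data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  # round outward to values exact in the 6-digit header field
  pmin <- -signif(-pmin + abs(pmin) * 1e-6 + 1e-12, 6)
  pmax <- signif(pmax + abs(pmax) * 1e-6 + 1e-12, 6)
  dmin <- -32768
  dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  header_bytes <- 256L + 256L * nchan
  wr(edf_pad("0", 8))
  wr(edf_pad(rec$participant_id, 80))
  wr(edf_pad(paste0("eegdyn age_code=", rec$age_code), 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(as.character(header_bytes), 8))
  wr(edf_pad("", 44))
  wr(edf_pad("1", 8))                                  # one data record
  wr(edf_num(nsamp / rec$fs, 8))                       # record duration (s)
  wr(edf_pad(as.character(nchan), 4))
  for (lab in rec$channel_labels) wr(edf_pad(lab, 16))
  for (i in seq_len(nchan)) wr(edf_pad("", 80))        # transducer
  for (i in seq_len(nchan)) wr(edf_pad("uV", 8))
  for (i in seq_len(nchan)) wr(edf_num(pmin[i]))
  for (i in seq_len(nchan)) wr(edf_num(pmax[i]))
  for (i in seq_len(nchan)) wr(edf_pad(as.character(dmin), 8))
  for (i in seq_len(nchan)) wr(edf_pad(as.character(dmax), 8))
  for (i in seq_len(nchan)) wr(edf_pad("", 80))        # prefilter
  for (i in seq_len(nchan)) wr(edf_pad(as.character(nsamp), 8))
  for (i in seq_len(nchan)) wr(edf_pad("", 32))
  for (i in seq_len(nchan)) {
    dig <- round((rec$data[i, ] - pmin[i]) / (pmax[i] - pmin[i]) *
                   (dmax - dmin) + dmin)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path, participant_id = NULL, age_code = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                   # version
  pid <- rd(80)
  recinfo <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nchan <- as.integer(rd(4))
  labels <- vapply(seq_len(nchan), function(i) rd(16), character(1))
  for (i in seq_len(nchan)) rd(80)
  for (i in seq_len(nchan)) rd(8)
  pmin <- vapply(seq_len(nchan), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(nchan), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nchan), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nchan), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nchan)) rd(80)
  nsamp <- vapply(seq_len(nchan), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nchan)) rd(32)
  data <- matrix(0, nrow = nchan, ncol = sum(nsamp[1]) * n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nchan)) {
      dig <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                     endian = "little")
      phys <- (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) +
        pmin[i]
      data[i, ((r - 1) * nsamp[i] + 1):(r * nsamp[i])] <- phys
    }
  }
  fs <- nsamp[1] / rec_dur
  age <- age_code
  if (is.null(age) && grepl("age_code=", recinfo)) {
    age <- suppressWarnings(
      as.integer(sub(".*age_code=(-?[0-9NA]+).*", "\\1", recinfo)))
  }
  eeg_recording(data, fs = fs, channel_labels = labels,
                participant_id = participant_id %||% pid,
                age_code = age %||% NA_integer_)
}

#' Read an EEG recording from EDF or delimited text
#'
#' Text files are tab-separated with a header row of channel labels (one
#' column per channel, one row per sample) and take the sampling rate from a
#' `<path>.json` sidecar or the `fs` argument. EDF files are standard
#' 16-bit European Data Format.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"edf"` or `"text"`.
#' @param fs Sampling rate override for text files without a sidecar.
#' @param participant_id,age_code Metadata overrides.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "text"), fs = NULL,
                           participant_id = NULL, age_code = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_recording: no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  }
  rec <- switch(format,
                edf = read_recording_edf(path, participant_id, age_code),
                text = read_recording_text(path, fs, participant_id, age_code))
  rec
}

#' Write an EEG recording to EDF or delimited text
#'
#' @param rec An `eeg_recording`.
#' @param path Output file.
#' @param format `"auto"` (by extension), `"edf"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("auto", "edf", "text")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "text"
  }
  switch(format,
         edf = write_recording_edf(rec, path),
         text = write_recording_text(rec, path))
  invisible(path)
}

# ---- montage ----------------------------------------------------------------

#' Montage map from dense-net channels to the 10-20 electrodes
#'
#' @param mapping Data frame with columns `target` (the 19 canonical 10-20
#'   labels) and `source` (channel label in the dense recording).
#' @return Object of class `montage_map`.
#' @export
montage_map <- function(mapping) {
  stopifnot(is.data.frame(mapping), all(c("target", "source") %in%
                                          names(mapping)))
  targets <- eegdyn_1020_labels()
  if (!setequal(mapping$target, targets) || nrow(mapping) != 19) {
    stop("montage_map: mapping must contain exactly the 19 canonical 10-20 ",
         "labels")
  }
  if (anyDuplicated(mapping$source)) {
    stop("montage_map: mapping must be injective (duplicate source channels)")
  }
  mapping <- mapping[match(targets, mapping$target), ]
  rownames(mapping) <- NULL
  structure(list(mapping = mapping, targets = targets),
            class = "montage_map")
}

#' Default HydroCel-style 128-channel to 10-20 montage map
#'
#' Reads the packaged editable table (`extdata/hydrocel_1020_map.csv`). The
#' assignment follows the commonly used correspondence between geodesic
#' sensor-net positions and the classical 10-20 sites; it is a configuration
#' file, not a fixed constant, and can be overridden per study with
#' [montage_map()] or the `--montage-map` CLI flag.
#'
#' @return A `montage_map`.
#' @export
default_montage_map <- function() {
  path <- system.file("extdata", "hydrocel_1020_map.csv", package = "eegdyn")
  montage_map(utils::read.table(path, header = TRUE, sep = ",",
                                stringsAsFactors = FALSE))
}

#' Select the 19 electrodes of the 10-20 montage
#'
#' Projects a dense-net recording onto the 19 classical 10-20 channels in
#' canonical order. For each target the mapped source channel is used; if the
#' source is absent but the recording already carries the target's own 10-20
#' label, that channel is taken instead (so recordings already in 10-20
#' layout pass through, possibly reordered).
#'
#' @param rec An `eeg_recording`.
#' @param map A `montage_map` (default [default_montage_map()]).
#' @return An `eeg_recording` with exactly 19 channels labelled
#'   `Fp1 ... O2`.
#' @export
select_1020_channels <- function(rec, map = default_montage_map()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(map, "montage_map"))
  idx <- integer(19)
  missing <- character(0)
  for (k in seq_len(19)) {
    target <- map$mapping$target[k]
    source <- map$mapping$source[k]
    i <- match(source, rec$channel_labels)
    if (is.na(i)) i <- match(target, rec$channel_labels)
    if (is.na(i)) missing <- c(missing, target) else idx[k] <- i
  }
  if (length(missing)) {
    stop("select_1020_channels: no source channel for 10-20 label(s): ",
         paste(missing, collapse = ", "))
  }
  eeg_recording(rec$data[idx, , drop = FALSE], fs = rec$fs,
                channel_labels = map$mapping$target,
                participant_id = rec$participant_id, age_code = rec$age_code)
}

#' Select a fixed-length analysis segment
#'
#' Takes the half-open sample window `[round(start_s * fs),
#' round(start_s * fs) + round(duration_s * fs))` from every channel
#' (0-based sample indexing).
#'
#' @param rec An `eeg_recording`.
#' @param start_s Window start in seconds (default 0).
#' @param duration_s Window length in seconds (default 30).
#' @return An `eeg_recording` with `round(duration_s * fs)` samples per
#'   channel.
#' @export
select_segment <- function(rec, start_s = 0, duration_s = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  i0 <- round(start_s * rec$fs)
  n <- round(duration_s * rec$fs)
  if (i0 < 0 || n <= 0 || i0 + n > ncol(rec$data)) {
    stop("select_segment: window [", start_s, ", ", start_s + duration_s,
         ") s is outside the recording (", ncol(rec$data) / rec$fs, " s)")
  }
  eeg_recording(rec$data[, (i0 + 1):(i0 + n), drop = FALSE], fs = rec$fs,
                channel_labels = rec$channel_labels,
                participant_id = rec$participant_id, age_code = rec$age_code)
}
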
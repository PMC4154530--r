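#' Construct an EEG recording object
#'
#' Container for a subject's multichannel EEG. Channels are stored as a named
#' list of numeric vectors in microvolts, all of equal length.
#'
#' @param signals named list of numeric vectors (microvolts), one per channel.
#' @param sample_rate_hz sampling rate in Hz (positive; 128 for the intended
#'   forehead montage).
#' @param subject_id subject identifier string.
#' @param start_time optional `POSIXct` start time.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, sample_rate_hz, subject_id = "S01",
                          start_time = NULL) {
  if (!is.list(signals) || length(signals) < 1)
    stop("`signals` must be a non-empty named list of numeric vectors")
  if (is.null(names(signals)) || any(!nzchar(names(signals))))
    stop("every channel in `signals` must be named")
  lens <- vapply(signals, length, integer(1))
  if (length(unique(lens)) != 1)
    stop("all channels must have equal length")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0)
    stop("`sample_rate_hz` must be a single positive number")
  structure(
    list(subject_id = as.character(subject_id),
         channel_names = names(signals),
         sample_rate_hz = as.numeric(sample_rate_hz),
         signals = lapply(signals, as.numeric),
         start_time = start_time),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  n <- length(x$signals[[1]])
  cat(sprintf("<eeg_recording> subject %s: %d channel(s) [%s], %.1f s @ %g Hz\n",
              x$subject_id, length(x$signals),
              paste(x$channel_names, collapse = ", "),
              n / x$sample_rate_hz, x$sample_rate_hz))
  invisible(x)
}

#' Recording duration in seconds
#' @param recording an [eeg_recording()].
#' @return duration in seconds.
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  length(recording$signals[[1]]) / recording$sample_rate_hz
}

# ---- EDF (European Data Format, 16-bit) ------------------------------------
#
# Plain EDF: one 256-byte fixed header, ns * 256 bytes of signal headers laid
# out field-major (all labels, then all transducer fields, ...), then data
# records of interleaved little-endian int16 samples. Digital-to-physical
# scaling is linear per signal.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = 3), 1, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Encodes each channel as 16-bit integers over the declared physical range
#' (linear digital-to-physical scaling, one data record per second). The
#' round-trip error through [read_edf()] is bounded by one digital
#' quantization step, `diff(physical_range) / 65535`.
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @param physical_range numeric length-2, declared physical min/max in
#'   microvolts; all sample amplitudes must lie inside it.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, physical_range = c(-500, 500)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (length(physical_range) != 2 || physical_range[1] >= physical_range[2])
    stop("`physical_range` must be c(min, max) with min < max")
  fs <- recording$sample_rate_hz
  if (abs(fs - round(fs)) > 1e-9)
    stop("write_edf requires an integer sample rate (1-s data records)")
  fs <- as.integer(round(fs))
  sigs <- recording$signals
  ns <- length(sigs)
  rng <- range(unlist(sigs, use.names = FALSE))
  if (rng[1] < physical_range[1] || rng[2] > physical_range[2])
    stop(sprintf("signal amplitude [%.3g, %.3g] exceeds declared physical range [%g, %g]",
                 rng[1], rng[2], physical_range[1], physical_range[2]))
  n <- length(sigs[[1]])
  n_rec <- n %/% fs
  if (n_rec < 1) stop("recording shorter than one 1-s data record")
  if (n_rec * fs != n) {
    warning(sprintf("truncating %d trailing samples (partial data record)",
                    n - n_rec * fs))
    sigs <- lapply(sigs, function(x) x[seq_len(n_rec * fs)])
  }
  # symmetric digital range: a symmetric physical range then has an exact
  # code for zero, so all-zero channels round-trip exactly
  dmin <- -32767L; dmax <- 32767L
  pmin <- physical_range[1]; pmax <- physical_range[2]
  gain <- (dmax - dmin) / (pmax - pmin)

  st <- recording$start_time
  if (is.null(st)) st <- as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(recording$subject_id, 80),
    edf_pad("sleepstager", 80),
    edf_pad(format(st, "%d.%m.%y"), 8),
    edf_pad(format(st, "%H.%M.%S"), 8),
    edf_pad(256L * (ns + 1L), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad("1", 8),
    edf_pad(ns, 4),
    # signal headers, field-major
    paste(edf_pad(recording$channel_names, 16), collapse = ""),
    paste(rep(edf_pad("", 80), ns), collapse = ""),
    paste(rep(edf_pad("uV", 8), ns), collapse = ""),
    paste(rep(edf_num(pmin, 8), ns), collapse = ""),
    paste(rep(edf_num(pmax, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmin, 8), ns), collapse = ""),
    paste(rep(edf_pad(dmax, 8), ns), collapse = ""),
    paste(rep(edf_pad("BP:0.5-50Hz", 80), ns), collapse = ""),
    paste(rep(edf_pad(fs, 8), ns), collapse = ""),
    paste(rep(edf_pad("", 32), ns), collapse = ""))

  dig <- lapply(sigs, function(x) {
    as.integer(pmin(pmax(round((x - pmin) * gain + dmin), dmin), dmax))
  })
  # interleave per record: record r holds fs samples of each signal in turn
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)
  blocks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    blocks[[r]] <- unlist(lapply(dig, function(d) d[idx[, r]]),
                          use.names = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  writeBin(unlist(blocks, use.names = FALSE), con, size = 2,
           endian = "little")
  invisible(path)
}

read_edf_header <- function(con, path) {
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  version <- trimws(rd(8))
  if (!identical(version, "0"))
    stop(sprintf("'%s' is not a valid EDF file (bad version field)", path))
  patient <- trimws(rd(80)); recid <- trimws(rd(80))
  date <- trimws(rd(8)); time <- trimws(rd(8))
  hdr_bytes <- as.integer(trimws(rd(8)))
  rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rec_dur <- as.numeric(trimws(rd(8)))
  ns <- as.integer(trimws(rd(4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || is.na(rec_dur) ||
      is.na(hdr_bytes) || hdr_bytes != 256L * (ns + 1L))
    stop(sprintf("'%s' has a malformed EDF header", path))
  rdn <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- rdn(16); rdn(80); dims <- rdn(8)
  pmin <- as.numeric(rdn(8)); pmax <- as.numeric(rdn(8))
  dmin <- as.numeric(rdn(8)); dmax <- as.numeric(rdn(8))
  rdn(80)
  spr <- as.integer(rdn(8)); rdn(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop(sprintf("'%s' has a malformed EDF signal header", path))
  list(patient = patient, recid = recid, date = date, time = time,
       n_rec = n_rec, rec_dur = rec_dur, ns = ns, labels = labels,
       pmin = pmin, pmax = pmax, dmin = dmin, dmax = dmax, spr = spr)
}

#' Read channels from an EDF file
#'
#' Reads a plain EDF (16-bit) file and returns the requested channels in
#' physical units (microvolts), applying each signal's declared
#' digital-to-physical scaling.
#'
#' @param path EDF file path.
#' @param channels character vector of channel labels to load, in the order
#'   they should appear in the result; `NULL` loads all channels.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channels = NULL) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con, path)
  if (is.null(channels)) channels <- h$labels
  sel <- match(channels, h$labels)
  if (anyNA(sel))
    stop(sprintf("channel(s) not present in '%s': %s (file has: %s)",
                 path, paste(channels[is.na(sel)], collapse = ", "),
                 paste(h$labels, collapse = ", ")))
  rates <- h$spr[sel] / h$rec_dur
  if (length(unique(rates)) != 1)
    stop("requested channels have unequal sample rates")
  raw <- readBin(con, integer(), n = h$n_rec * sum(h$spr), size = 2,
                 endian = "little")
  if (length(raw) < h$n_rec * sum(h$spr))
    stop(sprintf("'%s' is truncated: fewer samples than the header declares", path))
  offs <- c(0, cumsum(h$spr))
  rec_len <- sum(h$spr)
  out <- vector("list", length(sel))
  for (k in seq_along(sel)) {
    i <- sel[k]
    pos <- as.vector(outer(offs[i] + seq_len(h$spr[i]),
                           (seq_len(h$n_rec) - 1L) * rec_len, "+"))
    d <- raw[pos]
    gain <- (h$pmax[i] - h$pmin[i]) / (h$dmax[i] - h$dmin[i])
    out[[k]] <- (d - h$dmin[i]) * gain + h$pmin[i]
  }
  names(out) <- channels
  st <- tryCatch(
    as.POSIXct(paste(h$date, h$time), format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
    error = function(e) NULL)
  eeg_recording(out, sample_rate_hz = rates[1], subject_id = h$patient,
                start_time = st)
}
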
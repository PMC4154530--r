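#' Construct a single 30-s epoch signal
#'
#' The scoring unit: one fixed-duration block of the two forehead channels.
#' At 128 Hz a 30-s epoch holds 3840 samples per channel.
#'
#' @param channels named list of numeric vectors (microvolts), one per channel.
#' @param sample_rate_hz sampling rate in Hz.
#' @param epoch_index 0-based position of this epoch within its recording.
#' @param epoch_duration_s epoch length in seconds (default 30).
#' @return An object of class `epoch_signal`.
#' @export
epoch_signal <- function(channels, sample_rate_hz, epoch_index = 0L,
                         epoch_duration_s = 30) {
  if (!is.list(channels) || length(channels) < 1)
    stop("`channels` must be a non-empty named list")
  expected <- round(epoch_duration_s * sample_rate_hz)
  lens <- vapply(channels, length, integer(1))
  if (any(lens != expected))
    stop(sprintf("each channel must have exactly %d samples (%g s at %g Hz); got %s",
                 expected, epoch_duration_s, sample_rate_hz,
                 paste(lens, collapse = ", ")))
  if (epoch_index < 0) stop("`epoch_index` must be non-negative")
  structure(list(channels = lapply(channels, as.numeric),
                 sample_rate_hz = as.numeric(sample_rate_hz),
                 epoch_index = as.integer(epoch_index),
                 epoch_duration_s = as.numeric(epoch_duration_s)),
            class = "epoch_signal")
}

#' @export
print.epoch_signal <- function(x, ...) {
  cat(sprintf("<epoch_signal> #%d: %d channel(s) x %d samples @ %g Hz\n",
              x$epoch_index, length(x$channels),
              length(x$channels[[1]]), x$sample_rate_hz))
  invisible(x)
}

#' Cut a recording into labeled 30-s epochs
#'
#' Splits the recording into consecutive, non-overlapping fixed-duration
#' blocks; a trailing partial block is discarded (with a message). When a
#' hypnogram is supplied, epoch `i` is paired with label `i` (0-based, both
#' starting at the recording start); if the two disagree in length, the
#' excess of the longer is dropped with a warning, and a mismatch beyond
#' `tolerance_epochs` is an error.
#'
#' @param recording an [eeg_recording()].
#' @param hyp optional [hypnogram()].
#' @param epoch_duration_s epoch length in seconds.
#' @param tolerance_epochs maximum tolerated absolute difference between the
#'   number of full epochs and the number of labels.
#' @return A list with one element per epoch, each a list with components
#'   `epoch` (an [epoch_signal()]) and `stage` (a label, `"UNKNOWN"` when no
#'   hypnogram is given).
#' @export
segment_epochs <- function(recording, hyp = NULL, epoch_duration_s = 30,
                           tolerance_epochs = 5L) {
  stopifnot(inherits(recording, "eeg_recording"))
  fs <- recording$sample_rate_hz
  spe <- round(epoch_duration_s * fs)
  n <- length(recording$signals[[1]])
  n_epochs <- n %/% spe
  if (n_epochs < 1)
    stop(sprintf("recording (%.1f s) is shorter than one %g-s epoch",
                 n / fs, epoch_duration_s))
  if (n_epochs * spe != n)
    message(sprintf("discarding trailing partial epoch (%.1f s)",
                    (n - n_epochs * spe) / fs))
  stages <- rep("UNKNOWN", n_epochs)
  if (!is.null(hyp)) {
    stopifnot(inherits(hyp, "hypnogram"))
    n_lab <- length(hyp$stages)
    if (abs(n_lab - n_epochs) > tolerance_epochs)
      stop(sprintf("hypnogram (%d labels) and recording (%d epochs) differ by more than %d epochs",
                   n_lab, n_epochs, tolerance_epochs))
    if (n_lab != n_epochs)
      warning(sprintf("hypnogram has %d labels for %d epochs; using the first %d pairs",
                      n_lab, n_epochs, min(n_lab, n_epochs)))
    n_epochs <- min(n_lab, n_epochs)
    stages <- hyp$stages[seq_len(n_epochs)]
  }
  lapply(seq_len(n_epochs), function(i) {
    sel <- ((i - 1L) * spe + 1L):(i * spe)
    ch <- lapply(recording$signals, function(x) x[sel])
    list(epoch = epoch_signal(ch, fs, epoch_index = i - 1L,
                              epoch_duration_s = epoch_duration_s),
         stage = stages[i])
  })
}
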
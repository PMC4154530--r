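#' Band-pass filter specification
#'
#' Defaults follow the conventional sleep-EEG preprocessing band of
#' 0.5--50 Hz with a 4th-order Butterworth design applied forward-backward
#' (zero phase).
#'
#' @param low_cut_hz lower pass-band edge in Hz.
#' @param high_cut_hz upper pass-band edge in Hz.
#' @param order Butterworth design order per edge (the high-pass and
#'   low-pass sections are each of this order).
#' @param zero_phase apply the filter forward and backward so that the net
#'   group delay is zero (attenuations double in dB).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut_hz = 0.5, high_cut_hz = 50, order = 4L,
                        zero_phase = TRUE) {
  if (!(low_cut_hz > 0 && high_cut_hz > low_cut_hz))
    stop("need 0 < low_cut_hz < high_cut_hz")
  if (order < 1) stop("`order` must be a positive integer")
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 order = as.integer(order), zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# reflect padding: continues the signal by point reflection about each end,
# suppressing the filter's edge transient
pad_reflect <- function(x, p) {
  n <- length(x)
  p <- min(p, n - 1L)
  c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
}

apply_iir <- function(flt, x, pad, zero_phase) {
  xp <- pad_reflect(x, pad)
  y <- as.numeric(signal::filter(flt, xp))
  if (zero_phase) y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[(min(pad, length(x) - 1L) + 1L):(min(pad, length(x) - 1L) + length(x))]
}

#' Band-pass filter a 30-s epoch
#'
#' Applies a Butterworth high-pass / low-pass cascade to every channel.
#' With `zero_phase = TRUE` (default) each section runs forward and backward,
#' so the output has no group delay. Edge transients are suppressed by
#' reflect-padding with `3 * order` samples.
#'
#' @param epoch an [epoch_signal()].
#' @param spec a [filter_spec()].
#' @return The filtered [epoch_signal()], same shape.
#' @export
bandpass_filter <- function(epoch, spec = filter_spec()) {
  stopifnot(inherits(epoch, "epoch_signal"), inherits(spec, "filter_spec"))
  fs <- epoch$sample_rate_hz
  nyq <- fs / 2
  if (spec$high_cut_hz >= nyq)
    stop(sprintf("high_cut_hz (%g) must be below the Nyquist frequency (%g)",
                 spec$high_cut_hz, nyq))
  n <- length(epoch$channels[[1]])
  if (n <= 3L * spec$order)
    stop("epoch too short for stable filtering")
  hp <- signal::butter(spec$order, spec$low_cut_hz / nyq, type = "high")
  lp <- signal::butter(spec$order, spec$high_cut_hz / nyq, type = "low")
  pad <- 3L * spec$order
  out <- lapply(epoch$channels, function(x) {
    apply_iir(lp, apply_iir(hp, x, pad, spec$zero_phase), pad, spec$zero_phase)
  })
  epoch_signal(out, fs, epoch$epoch_index, epoch$epoch_duration_s)
}
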
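#' Standard EEG frequency bands used by the feature extractor
#'
#' Band edges (Hz, inclusive on both ends at the 1-Hz bin resolution of a
#' 1-s analysis window): lower delta 1--2, delta 1--4, theta 5--7, alpha
#' 8--12, sigma 12--14, beta 15--30, gamma 30--50. Lower delta carries the
#' slow-wave information, sigma the spindle information, delta the K-complex
#' information.
#'
#' @return Named list of `c(low_hz, high_hz)` pairs.
#' @export
default_bands <- function() {
  list(lower_delta = c(1, 2), delta = c(1, 4), theta = c(5, 7),
       alpha = c(8, 12), sigma = c(12, 14), beta = c(15, 30),
       gamma = c(30, 50))
}

#' Short-time Fourier power spectral density of one channel
#'
#' Slides a Hamming window of `window_s` seconds in steps of `step_s`
#' seconds over the signal and computes a one-sided periodogram for every
#' segment. A 30-s epoch at 128 Hz with the default 1-s window and 0.5-s
#' step yields 59 segments with 1-Hz bin spacing.
#'
#' @param x numeric signal vector (one channel).
#' @param sample_rate_hz sampling rate in Hz.
#' @param window_s window length in seconds; `window_s * sample_rate_hz`
#'   must be a whole number of samples.
#' @param step_s hop between consecutive windows in seconds.
#' @return An object of class `segment_spectrogram` with fields `psd`
#'   (`n_segments x n_bins` matrix), `bin_freqs_hz` and `normalized = FALSE`.
#' @export
stft_psd <- function(x, sample_rate_hz, window_s = 1, step_s = 0.5) {
  W <- window_s * sample_rate_hz
  if (abs(W - round(W)) > 1e-9)
    stop("`window_s * sample_rate_hz` must be an integer number of samples")
  W <- as.integer(round(W))
  S <- as.integer(round(step_s * sample_rate_hz))
  if (S < 1) stop("`step_s` too small: hop below one sample")
  L <- length(x)
  if (L < W) stop("signal shorter than the analysis window")
  n_seg <- (L - W) %/% S + 1L
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(W - 1)) / (W - 1))
  scale <- 1 / (sample_rate_hz * sum(w^2))
  n_bins <- W %/% 2L + 1L
  psd <- matrix(0, n_seg, n_bins)
  for (i in seq_len(n_seg)) {
    seg <- x[((i - 1L) * S + 1L):((i - 1L) * S + W)] * w
    X <- stats::fft(seg)[seq_len(n_bins)]
    p <- (Mod(X)^2) * scale
    # one-sided: double everything except DC and (for even W) Nyquist
    dbl <- rep(2, n_bins); dbl[1] <- 1
    if (W %% 2L == 0L) dbl[n_bins] <- 1
    psd[i, ] <- p * dbl
  }
  structure(list(psd = psd,
                 bin_freqs_hz = (0:(n_bins - 1L)) * sample_rate_hz / W,
                 normalized = FALSE),
            class = "segment_spectrogram")
}

#' @export
print.segment_spectrogram <- function(x, ...) {
  cat(sprintf("<segment_spectrogram> %d segments x %d bins (0-%g Hz)%s\n",
              nrow(x$psd), ncol(x$psd), max(x$bin_freqs_hz),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Normalize each spectrogram segment to unit total power
#'
#' Divides every frequency bin of a segment by that segment's total PSD, so
#' each row becomes a proportion spectrum summing to 1. This removes
#' amplitude (gain) differences between individuals, which is why all
#' downstream band features are scale invariant.
#'
#' @param spec a [stft_psd()] result (not yet normalized).
#' @return The normalized `segment_spectrogram`.
#' @export
normalize_segments <- function(spec) {
  stopifnot(inherits(spec, "segment_spectrogram"))
  if (spec$normalized) stop("spectrogram is already normalized")
  tot <- rowSums(spec$psd)
  if (any(!is.finite(tot)) || any(tot <= 0))
    stop("degenerate input: a segment has zero (or non-finite) total power")
  spec$psd <- spec$psd / tot
  spec$normalized <- TRUE
  spec
}

#' Relative band power of every segment
#'
#' Sums the normalized PSD over all frequency bins with
#' `low_hz <= f <= high_hz` (both edges inclusive), giving one relative
#' power value per segment.
#'
#' @param spec a normalized [segment_spectrogram][stft_psd].
#' @param band numeric `c(low_hz, high_hz)`.
#' @return Numeric vector, one value in `[0, 1]` per segment.
#' @export
band_power_series <- function(spec, band) {
  stopifnot(inherits(spec, "segment_spectrogram"))
  if (!spec$normalized) stop("spectrogram must be normalized first")
  if (length(band) != 2 || band[1] >= band[2])
    stop("`band` must be c(low_hz, high_hz) with low < high")
  sel <- spec$bin_freqs_hz >= band[1] & spec$bin_freqs_hz <= band[2]
  if (!any(sel))
    stop(sprintf("band [%g, %g] Hz covers no frequency bins", band[1], band[2]))
  rowSums(spec$psd[, sel, drop = FALSE])
}

#' Mean of the upper or lower fraction of sorted values
#'
#' Sorts the values and averages the first `k = max(1, floor(fraction * n))`
#' of them, descending for `which = "upper"` and ascending for
#' `which = "lower"`. This is the "average PSD of the upper/lower X% of
#' segments" statistic used by several stage features.
#'
#' @param values numeric vector.
#' @param fraction fraction in `(0, 1]`.
#' @param which `"upper"` or `"lower"`.
#' @return A single number.
#' @export
sorted_fraction_mean <- function(values, fraction, which = c("upper", "lower")) {
  which <- match.arg(which)
  if (length(values) == 0) stop("`values` must be non-empty")
  if (!(fraction > 0 && fraction <= 1)) stop("`fraction` must be in (0, 1]")
  k <- max(1L, floor(fraction * length(values)))
  s <- sort(values, decreasing = (which == "upper"))
  mean(s[seq_len(k)])
}

#' Maximum and remaining-segment mean
#'
#' Returns the maximum of the vector and the mean of all values with one
#' occurrence of the maximum removed — the transient-event statistic used
#' for spindles (sigma band) and K-complexes (delta band): a single strong
#' segment raises the max while the rest-mean tracks the background.
#'
#' @param values numeric vector of length at least 2.
#' @return Named numeric `c(max = ..., rest_mean = ...)`.
#' @export
max_and_rest_mean <- function(values) {
  n <- length(values)
  if (n < 2) stop("`values` must have length >= 2")
  m <- max(values)
  c(max = m, rest_mean = (sum(values) - m) / (n - 1))
}

knowledge_stats <- c("lower_delta_upper80", "lower_delta_lower80",
                     "delta_max", "delta_rest",
                     "theta_upper50", "theta_lower50",
                     "alpha_upper50", "alpha_lower50",
                     "sigma_max", "sigma_rest",
                     "beta_upper50", "beta_lower50",
                     "gamma_mean")

knowledge_channel_features <- function(series) {
  c(sorted_fraction_mean(series$lower_delta, 0.8, "upper"),
    sorted_fraction_mean(series$lower_delta, 0.8, "lower"),
    max_and_rest_mean(series$delta),
    sorted_fraction_mean(series$theta, 0.5, "upper"),
    sorted_fraction_mean(series$theta, 0.5, "lower"),
    sorted_fraction_mean(series$alpha, 0.5, "upper"),
    sorted_fraction_mean(series$alpha, 0.5, "lower"),
    max_and_rest_mean(series$sigma),
    sorted_fraction_mean(series$beta, 0.5, "upper"),
    sorted_fraction_mean(series$beta, 0.5, "lower"),
    mean(series$gamma))
}

#' Knowledge-based spectral features of one epoch
#'
#' Implements the scoring-rule-guided extractor: per channel, the epoch is
#' decomposed into 59 per-segment normalized spectra ([stft_psd()] +
#' [normalize_segments()]) and summarized into 13 band statistics chosen to
#' mirror how experts score stages visually:
#'
#' * lower delta (slow waves, N3): means of the upper and lower 80% of
#'   segments;
#' * delta (K-complex, N2): segment maximum and remaining-58 mean;
#' * theta (light sleep N1/N2/REM): means of the upper and lower 50%;
#' * alpha (relaxed wake): means of the upper and lower 50%;
#' * sigma (sleep spindle, N2): segment maximum and remaining-58 mean;
#' * beta (alert wake): means of the upper and lower 50%;
#' * gamma (movement/muscle artifact): overall mean.
#'
#' All values are relative powers in `[0, 1]`; multiplying the raw epoch by
#' any positive constant leaves the vector unchanged.
#'
#' @param epoch a (band-pass filtered) [epoch_signal()].
#' @param bands band list as from [default_bands()].
#' @param window_s,step_s STFT segmentation parameters.
#' @return Named numeric vector of `13 * n_channels` features; names are
#'   `<channel>.<band_statistic>`.
#' @export
extract_knowledge_features <- function(epoch, bands = default_bands(),
                                       window_s = 1, step_s = 0.5) {
  stopifnot(inherits(epoch, "epoch_signal"))
  need <- c("lower_delta", "delta", "theta", "alpha", "sigma", "beta", "gamma")
  missing_b <- setdiff(need, names(bands))
  if (length(missing_b) > 0)
    stop("`bands` is missing: ", paste(missing_b, collapse = ", "))
  out <- lapply(names(epoch$channels), function(ch) {
    spec <- normalize_segments(stft_psd(epoch$channels[[ch]],
                                        epoch$sample_rate_hz,
                                        window_s, step_s))
    series <- lapply(bands[need], function(b) band_power_series(spec, b))
    v <- knowledge_channel_features(series)
    names(v) <- paste(ch, knowledge_stats, sep = ".")
    v
  })
  unlist(out)
}

#' Conventional whole-epoch PSD features of one epoch
#'
#' The baseline extractor: one periodogram of the entire 30-s signal per
#' channel, aggregated into 50 one-Hz bands centered at 1..50 Hz and (by
#' default) divided by the total 1--50 Hz power so the 50 values sum to 1.
#' Short transients such as spindles are diluted across the whole epoch
#' here, which is precisely the weakness the segment-based extractor
#' addresses.
#'
#' @param epoch a (band-pass filtered) [epoch_signal()].
#' @param normalize divide by total 1--50 Hz power (default `TRUE`); set
#'   `FALSE` for the raw band PSD.
#' @return Named numeric vector of `50 * n_channels` features
#'   (`<channel>.psd_<k>hz`).
#' @export
extract_conventional_features <- function(epoch, normalize = TRUE) {
  stopifnot(inherits(epoch, "epoch_signal"))
  fs <- epoch$sample_rate_hz
  out <- lapply(names(epoch$channels), function(ch) {
    x <- epoch$channels[[ch]]
    n <- length(x)
    X <- stats::fft(x)[seq_len(n %/% 2L + 1L)]
    p <- Mod(X)^2 / (fs * n)
    dbl <- rep(2, length(p)); dbl[1] <- 1
    if (n %% 2L == 0L) dbl[length(p)] <- 1
    p <- p * dbl
    f <- (seq_along(p) - 1) * fs / n
    v <- vapply(1:50, function(b) sum(p[f >= b - 0.5 & f < b + 0.5]),
                numeric(1))
    tot <- sum(v)
    if (normalize) {
      if (tot <= 0) stop("degenerate input: epoch has zero power in 1-50 Hz")
      v <- v / tot
    }
    names(v) <- paste0(ch, ".psd_", 1:50, "hz")
    v
  })
  unlist(out)
}

#' Feature table for a set of labeled epochs
#'
#' Applies the band-pass filter and one of the two extractors to every
#' epoch, returning a data frame ready for classification: columns
#' `subject_id`, `epoch_index`, `stage`, then one column per feature.
#'
#' @param pairs list of `list(epoch=, stage=)` as returned by
#'   [segment_epochs()].
#' @param subject_id subject identifier recorded in the table.
#' @param mode `"knowledge"` or `"conventional"`.
#' @param filter a [filter_spec()], or `NULL` to skip filtering.
#' @param bands band list for the knowledge extractor.
#' @return A `data.frame`.
#' @export
feature_table <- function(pairs, subject_id = "S01",
                          mode = c("knowledge", "conventional"),
                          filter = filter_spec(), bands = default_bands()) {
  mode <- match.arg(mode)
  rows <- lapply(pairs, function(p) {
    ep <- p$epoch
    if (!is.null(filter)) ep <- bandpass_filter(ep, filter)
    if (mode == "knowledge") extract_knowledge_features(ep, bands)
    else extract_conventional_features(ep)
  })
  feat <- do.call(rbind, rows)
  data.frame(subject_id = subject_id,
             epoch_index = vapply(pairs, function(p) p$epoch$epoch_index,
                                  integer(1)),
             stage = vapply(pairs, function(p) p$stage, character(1)),
             feat, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Names of the feature columns of a feature table
#' @param features a data frame from [feature_table()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(colnames(features), c("subject_id", "epoch_index", "stage"))
}
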
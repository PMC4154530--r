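# Fixtures shared across test files. Everything is generated in code at
# test time; seeds are explicit so failures reproduce.

fs_default <- 128

# deterministic multi-tone epoch: sum of sines at the given frequencies
tone_epoch <- function(freqs, amps = rep(10, length(freqs)), fs = fs_default,
                       duration = 30, channels = c("FP1", "FP2")) {
  t <- (0:(duration * fs - 1)) / fs
  x <- rowSums(vapply(seq_along(freqs),
                      function(i) amps[i] * sin(2 * pi * freqs[i] * t),
                      numeric(length(t))))
  sig <- stats::setNames(list(x, x), channels)
  epoch_signal(sig, fs)
}

# small noisy epoch with per-channel noise (for EDF round trips etc.)
noise_epoch <- function(seed = 1, fs = fs_default, amp = 20) {
  set.seed(seed)
  epoch_signal(list(FP1 = amp * stats::rnorm(30 * fs),
                    FP2 = amp * stats::rnorm(30 * fs)), fs)
}

# two well-separated Gaussian blobs in 2-D, labels 0/1
blob_fixture <- function(n = 40, sep = 2, sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n, -sep, sd), n / 2, 2),
             matrix(stats::rnorm(n, sep, sd), n / 2, 2))
  list(X = X, y = rep(c(0, 1), each = n / 2))
}

# XOR pattern: four clusters, label = sign of the quadrant product
xor_fixture <- function(n = 80, sd = 0.25, seed = 2) {
  set.seed(seed)
  cx <- rep(c(-1, 1, -1, 1), each = n / 4)
  cy <- rep(c(-1, -1, 1, 1), each = n / 4)
  X <- cbind(cx + stats::rnorm(n, 0, sd), cy + stats::rnorm(n, 0, sd))
  list(X = X, y = as.numeric(cx * cy > 0))
}

# five well-separated Gaussian blobs labeled with the five stages
five_blob_fixture <- function(n_per = 30, sd = 0.3, seed = 3) {
  set.seed(seed)
  centers <- matrix(c(0, 0, 4, 0, 0, 4, -4, 0, 0, -4), ncol = 2, byrow = TRUE)
  X <- do.call(rbind, lapply(1:5, function(i)
    cbind(stats::rnorm(n_per, centers[i, 1], sd),
          stats::rnorm(n_per, centers[i, 2], sd))))
  list(X = X, y = rep(SLEEP_STAGES, each = n_per))
}

# small labeled synthetic feature table for LOSO tests (no EEG simulation:
# features drawn around stage-specific centroids, per-subject offsets)
toy_feature_table <- function(n_subjects = 3, epochs = 40, d = 4, seed = 4) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(5 * d, sd = 3), 5, d)
  rownames(centers) <- SLEEP_STAGES
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    stages <- sample(SLEEP_STAGES, epochs, replace = TRUE)
    # make sure every stage appears for every subject
    stages[1:5] <- SLEEP_STAGES
    offs <- stats::rnorm(d, sd = 0.3)
    X <- centers[stages, , drop = FALSE] +
      matrix(stats::rnorm(epochs * d, sd = 0.6), epochs, d) +
      matrix(offs, epochs, d, byrow = TRUE)
    colnames(X) <- paste0("f", seq_len(d))
    data.frame(subject_id = sprintf("S%02d", s),
               epoch_index = seq_len(epochs) - 1L, stage = stages, X,
               stringsAsFactors = FALSE)
  }))
}
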
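# STFT spectrogram, per-segment normalization, band statistics, extractors

# direct O(n^2) DFT of a windowed segment: independent oracle for stft_psd
dft_psd_oracle <- function(x, fs) {
  n <- length(x)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  xw <- x * w
  nb <- n %/% 2 + 1
  p <- numeric(nb)
  for (k in 0:(nb - 1)) {
    re <- sum(xw * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(xw * sin(-2 * pi * k * (0:(n - 1)) / n))
    p[k + 1] <- (re^2 + im^2) / (fs * sum(w^2))
  }
  dbl <- rep(2, nb); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nb] <- 1
  p * dbl
}

test_that("a 30-s epoch at 128 Hz yields 59 segments with 1-Hz bins", {
  set.seed(1)
  sp <- stft_psd(stats::rnorm(3840), 128)
  expect_identical(nrow(sp$psd), 59L)
  expect_equal(sp$bin_freqs_hz, 0:64)
  expect_false(sp$normalized)
})

test_that("segment count follows floor((L-W)/S)+1 for arbitrary geometry", {
  brute_count <- function(L, W, S) {
    n <- 0L; start <- 1L
    while (start + W - 1L <= L) { n <- n + 1L; start <- start + S }
    n
  }
  set.seed(2)
  for (i in 1:20) {
    L <- sample(64:1000, 1); W <- sample(16:64, 1); S <- sample(1:32, 1)
    if (L < W) next
    sp <- stft_psd(stats::rnorm(L), sample_rate_hz = W, window_s = 1,
                   step_s = S / W)
    expect_identical(nrow(sp$psd), brute_count(L, W, S))
  }
})

test_that("single-segment PSD matches the direct DFT oracle to 1e-9", {
  set.seed(3)
  x <- stats::rnorm(128)
  sp <- stft_psd(x, 128)
  expect_equal(as.numeric(sp$psd[1, ]), dft_psd_oracle(x, 128),
               tolerance = 1e-9)
})

test_that("a pure 10 Hz sine peaks at the 10 Hz bin in every segment", {
  ep <- tone_epoch(10, 1)
  sp <- stft_psd(ep$channels$FP1, 128)
  peaks <- sp$bin_freqs_hz[apply(sp$psd, 1, which.max)]
  expect_true(all(peaks == 10))
})

test_that("normalization makes each segment sum to one and is scale invariant", {
  set.seed(4)
  x <- stats::rnorm(3840)
  ns <- normalize_segments(stft_psd(x, 128))
  expect_true(ns$normalized)
  expect_equal(rowSums(ns$psd), rep(1, 59), tolerance = 1e-9)
  ns3 <- normalize_segments(stft_psd(3 * x, 128))
  expect_equal(ns$psd, ns3$psd, tolerance = 1e-12)
  expect_error(normalize_segments(ns), "already")
  expect_error(normalize_segments(stft_psd(rep(0, 3840), 128)), "degenerate")
})

test_that("band power series behave as sums over disjoint subsets of a unit row", {
  set.seed(5)
  ns <- normalize_segments(stft_psd(stats::rnorm(3840), 128))
  expect_equal(band_power_series(ns, c(0, 64)), rep(1, 59), tolerance = 1e-9)
  th <- band_power_series(ns, c(5, 7)); al <- band_power_series(ns, c(8, 12))
  expect_true(all(th + al <= 1 + 1e-12))
  expect_true(all(th >= 0 & al >= 0))
  expect_error(band_power_series(ns, c(70, 80)), "no frequency bins")
  expect_error(band_power_series(stft_psd(stats::rnorm(3840), 128), c(5, 7)),
               "normalized")
})

test_that("a pure 13 Hz sine concentrates >0.9 of every segment in sigma", {
  ep <- tone_epoch(13, 10)
  ns <- normalize_segments(stft_psd(ep$channels$FP1, 128))
  expect_true(all(band_power_series(ns, c(12, 14)) > 0.9))
})

test_that("sorted_fraction_mean and max_and_rest_mean match hand values and arithmetic oracles", {
  expect_equal(sorted_fraction_mean(1:10, 0.5, "upper"), 8)
  expect_equal(sorted_fraction_mean(1:10, 0.5, "lower"), 3)
  expect_equal(sorted_fraction_mean(rep(4.2, 59), 0.8, "upper"), 4.2)
  expect_error(sorted_fraction_mean(numeric(0), 0.5), "non-empty")

  expect_equal(max_and_rest_mean(c(rep(2, 58), 10)),
               c(max = 10, rest_mean = 2))
  expect_equal(max_and_rest_mean(rep(3, 10)), c(max = 3, rest_mean = 3))
  set.seed(6)
  v <- stats::rnorm(59)
  expect_equal(max_and_rest_mean(v)[["rest_mean"]],
               (sum(v) - max(v)) / (length(v) - 1))
  expect_error(max_and_rest_mean(1), "length")

  # sorted-mean monotonicity: upper fraction mean >= lower fraction mean
  for (i in 1:10) {
    v <- stats::rnorm(59)
    expect_gte(sorted_fraction_mean(v, 0.8, "upper"),
               sorted_fraction_mean(v, 0.8, "lower"))
  }
})

test_that("knowledge extractor yields 26 named features in [0,1], scale invariant and deterministic", {
  ep <- noise_epoch(seed = 8)
  f <- extract_knowledge_features(ep)
  expect_length(f, 26)
  expect_true(all(grepl("^FP[12]\\.", names(f))))
  expect_true(all(f >= 0 & f <= 1))
  # band max always >= band rest-mean
  expect_gte(f[["FP1.sigma_max"]], f[["FP1.sigma_rest"]])
  expect_gte(f[["FP1.delta_max"]], f[["FP1.delta_rest"]])
  expect_gte(f[["FP1.lower_delta_upper80"]], f[["FP1.lower_delta_lower80"]])

  scaled <- ep
  scaled$channels <- lapply(ep$channels, function(x) 10 * x)
  expect_equal(extract_knowledge_features(scaled), f, tolerance = 1e-9)
  expect_identical(extract_knowledge_features(ep), f)  # bit-identical rerun
})

test_that("an injected 1-s spindle raises sigma-max but barely moves sigma rest-mean", {
  set.seed(9)
  fs <- 128
  t <- (0:(30 * fs - 1)) / fs
  bg <- 20 * sin(2 * pi * 6 * t + stats::runif(1, 0, 2 * pi)) +
    5 * stats::rnorm(length(t))
  spindle <- numeric(length(t))
  sel <- (10 * fs):(11 * fs - 1)
  spindle[sel] <- 30 * sin(2 * pi * 13 * t[sel]) *
    0.5 * (1 - cos(2 * pi * seq_along(sel) / length(sel)))
  mk <- function(x) epoch_signal(list(FP1 = x, FP2 = x), fs)
  f_with <- extract_knowledge_features(mk(bg + spindle))
  f_without <- extract_knowledge_features(mk(bg))
  expect_gt(f_with[["FP1.sigma_max"]], f_without[["FP1.sigma_max"]])
  expect_lt(abs(f_with[["FP1.sigma_rest"]] - f_without[["FP1.sigma_rest"]]),
            0.05)
})

test_that("conventional extractor yields 50 normalized one-Hz features per channel", {
  ep <- noise_epoch(seed = 10)
  f <- extract_conventional_features(ep)
  expect_length(f, 100)
  expect_equal(sum(f[grepl("^FP1", names(f))]), 1, tolerance = 1e-9)
  expect_equal(sum(f[grepl("^FP2", names(f))]), 1, tolerance = 1e-9)

  f10 <- extract_conventional_features(tone_epoch(10, 5))
  ch1 <- f10[grepl("^FP1", names(f10))]
  expect_identical(names(ch1)[which.max(ch1)], "FP1.psd_10hz")

  scaled <- ep
  scaled$channels <- lapply(ep$channels, function(x) 7 * x)
  expect_equal(extract_conventional_features(scaled), f, tolerance = 1e-9)
})

test_that("feature_table assembles metadata plus the feature schema", {
  set.seed(12)
  cfg <- simulation_config(n_subjects = 2, epochs_per_subject = 3, seed = 5)
  sub <- simulate_subject(cfg, 1)
  pairs <- segment_epochs(sub$recording, sub$hypnogram)
  ft <- feature_table(pairs, "S01", "knowledge")
  expect_identical(colnames(ft)[1:3], c("subject_id", "epoch_index", "stage"))
  expect_length(feature_columns(ft), 26)
  expect_identical(nrow(ft), 3L)
})
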
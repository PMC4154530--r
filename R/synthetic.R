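#' Stage recipe for the synthetic EEG generator
#'
#' Describes how to synthesize a 30-s two-channel epoch of one sleep stage:
#' a dominant band-limited rhythm present over a fraction of the epoch
#' (occupancy), always-on background carriers, transient events (spindles,
#' K-complexes, slow-wave bursts, eye movements), and a 1/f-plus-white
#' noise floor. Amplitudes are root-mean-square microvolts.
#'
#' @param stage stage label the recipe emulates.
#' @param dominant list `list(band = c(low, high), amp = , occupancy = )`;
#'   the dominant rhythm is windowed to a random contiguous stretch of the
#'   epoch (raised-cosine edges). `occupancy` is either a single fraction
#'   or a range `c(min, max)` from which each epoch draws its own
#'   occupancy — the scoring rules state minimum occupancies ("more than
#'   50% of the epoch"), so real epochs spread above the threshold.
#' @param background list of `list(band = , amp = )` carriers present for
#'   the whole epoch.
#' @param amp_jitter_sd SD of the per-epoch log-normal jitter applied
#'   independently to every component amplitude, emulating the
#'   nonstationarity of real EEG from one epoch to the next.
#' @param events list of `list(type = , rate = , dur = c(min, max),
#'   amp = )`; `type` is one of `"spindle"`, `"k_complex"`, `"slow_wave"`,
#'   `"eye_movement"`; `rate` is the Poisson mean number of events per
#'   epoch; durations are seconds.
#' @param pink_amp,white_amp noise-floor amplitudes; the white component is
#'   drawn independently per channel, everything else is shared between the
#'   near-symmetric FP1/FP2 sites (eye movements are shared but
#'   anti-correlated: opposite sign on the two channels).
#' @return An object of class `stage_recipe`.
#' @export
stage_recipe <- function(stage, dominant, background = list(),
                         events = list(), pink_amp = 18, white_amp = 6,
                         amp_jitter_sd = 0.3) {
  check_stages(stage, allow_unknown = FALSE)
  stopifnot(is.list(dominant), length(dominant$band) == 2,
            dominant$amp >= 0)
  if (length(dominant$occupancy) == 1)
    dominant$occupancy <- rep(dominant$occupancy, 2)
  if (any(dominant$occupancy < 0) || any(dominant$occupancy > 1) ||
      dominant$occupancy[1] > dominant$occupancy[2])
    stop("`dominant$occupancy` must be a fraction or range within [0, 1]")
  for (ev in events) {
    if (!ev$type %in% c("spindle", "k_complex", "slow_wave", "eye_movement"))
      stop("unknown event type: ", ev$type)
    if (ev$rate < 0 || any(ev$dur <= 0) || ev$dur[2] > 30 || ev$amp < 0)
      stop("invalid event parameters for type ", ev$type)
  }
  structure(list(stage = stage, dominant = dominant,
                 background = background, events = events,
                 pink_amp = pink_amp, white_amp = white_amp,
                 amp_jitter_sd = amp_jitter_sd),
            class = "stage_recipe")
}

#' Default stage recipes encoding the AASM scoring rules
#'
#' One recipe per stage, each parameter traceable to the visual scoring
#' rule the feature extractor targets. Occupancies are ranges whose lower
#' end is the rule's threshold (the rules state minimums, e.g. "more than
#' 50% of the epoch"), and every component amplitude receives per-epoch
#' log-normal jitter, so within-stage spectra are nonstationary as in real
#' EEG:
#' * **W** — alpha (8--12 Hz) rhythm over 50--95% of the epoch (rule:
#'   > 50% alpha), light beta background.
#' * **N1** — alpha attenuated and replaced by low-amplitude theta
#'   (5--7 Hz) over 50--95% of the epoch (rule: > 50% theta).
#' * **N2** — theta background with sleep spindles (12--14 Hz bursts of
#'   0.5--1.5 s) and K-complexes (biphasic transients >= 0.5 s), each at a
#'   mean rate of 0.5 per epoch (roughly one event every two epochs).
#' * **N3** — high-amplitude slow-wave activity (0.5--2 Hz) over 20--50%
#'   of the epoch (rule: > 20% occupancy, > 75 uV peak-to-peak: RMS 35 uV
#'   gives ~99 uV peak-to-peak).
#' * **REM** — theta background with large slow eye-movement deflections
#'   (< 2 Hz), which the frontopolar sites pick up with opposite polarity;
#'   the eye-movement rate is a free parameter (no quantitative AASM EEG
#'   rule exists for REM on these channels).
#'
#' @return Named list of [stage_recipe()] objects.
#' @export
default_recipes <- function() {
  list(
    W = stage_recipe("W",
      dominant = list(band = c(8, 12), amp = 25, occupancy = c(0.5, 0.95)),
      background = list(list(band = c(15, 30), amp = 6))),
    N1 = stage_recipe("N1",
      dominant = list(band = c(5, 7), amp = 20, occupancy = c(0.5, 0.95)),
      background = list(list(band = c(8, 12), amp = 5))),
    N2 = stage_recipe("N2",
      dominant = list(band = c(5, 7), amp = 20, occupancy = c(0.5, 0.95)),
      events = list(
        list(type = "spindle", rate = 0.5, dur = c(0.5, 1.5), amp = 30),
        list(type = "k_complex", rate = 0.5, dur = c(0.5, 1.0), amp = 80))),
    N3 = stage_recipe("N3",
      dominant = list(band = c(0.5, 2), amp = 35, occupancy = c(0.2, 0.5)),
      background = list(list(band = c(5, 7), amp = 8))),
    REM = stage_recipe("REM",
      dominant = list(band = c(5, 7), amp = 18, occupancy = c(0.5, 0.95)),
      background = list(list(band = c(15, 30), amp = 4)),
      events = list(
        list(type = "eye_movement", rate = 3, dur = c(0.5, 1.5), amp = 60))))
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_subjects number of subjects.
#' @param epochs_per_subject epochs per night.
#' @param stage_prevalence named probabilities for the five stages; the
#'   default is the pooled stage distribution of a typical healthy-adult
#'   overnight cohort: W 18.4%, N1 13.1%, N2 37.8%, N3 15.6%, REM 15.1%.
#' @param recipes per-stage [stage_recipe()] list.
#' @param jitter_sd SD of the per-subject multiplicative (log-normal)
#'   amplitude jitter emulating inter-individual gain differences — the
#'   nuisance the per-segment PSD normalization is designed to remove.
#' @param seed master seed; per-subject substreams are derived from it.
#' @param sample_rate_hz sampling rate.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(n_subjects = 10L, epochs_per_subject = 300L,
                              stage_prevalence = c(W = 0.184, N1 = 0.131,
                                                   N2 = 0.378, N3 = 0.156,
                                                   REM = 0.151),
                              recipes = default_recipes(),
                              jitter_sd = 0.2, seed = 1L,
                              sample_rate_hz = 128) {
  if (epochs_per_subject < 1) stop("`epochs_per_subject` must be >= 1")
  if (!setequal(names(stage_prevalence), SLEEP_STAGES))
    stop("`stage_prevalence` must be named with the five stages")
  p <- stage_prevalence[SLEEP_STAGES]
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("`stage_prevalence` must be non-negative and sum to 1")
  structure(list(n_subjects = as.integer(n_subjects),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 stage_prevalence = p / sum(p),
                 recipes = recipes, jitter_sd = jitter_sd,
                 seed = as.integer(seed),
                 sample_rate_hz = sample_rate_hz),
            class = "sim_config")
}

# band-limited unit-RMS Gaussian noise via Fourier masking
band_noise <- function(n, fs, band) {
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * fs / n
  mask <- abs(f) >= band[1] & abs(f) <= band[2]
  if (!any(mask)) stop(sprintf("band [%g, %g] Hz is empty at this length",
                               band[1], band[2]))
  X <- stats::fft(stats::rnorm(n))
  x <- Re(stats::fft(X * mask, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r == 0) return(x)
  x / r
}

# 1/f ("pink") unit-RMS noise, flat below 0.5 Hz
pink_noise <- function(n, fs) {
  f <- abs(c(0:(n %/% 2), -((n - n %/% 2 - 1):1))) * fs / n
  shape <- 1 / sqrt(pmax(f, 0.5))
  shape[1] <- 0
  X <- stats::fft(stats::rnorm(n)) * shape
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

# raised-cosine occupancy envelope over a random contiguous window
occupancy_envelope <- function(n, fs, occupancy) {
  if (occupancy >= 1) return(rep(1, n))
  L <- max(1L, round(occupancy * n))
  start <- sample.int(n - L + 1L, 1L)
  env <- numeric(n)
  env[start:(start + L - 1L)] <- 1
  ramp <- min(round(0.5 * fs), L %/% 2L)
  if (ramp > 1) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
    env[start:(start + ramp - 1L)] <- up
    env[(start + L - ramp):(start + L - 1L)] <- rev(up)
  }
  env
}

event_waveform <- function(type, dur, amp, fs) {
  m <- max(2L, round(dur * fs))
  t <- (seq_len(m) - 1) / fs
  switch(type,
    spindle = {
      freq <- stats::runif(1, 12, 14)
      hann <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
      amp * sqrt(2) * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi)) * hann
    },
    k_complex = -amp * sqrt(2) * sin(2 * pi * t / dur),
    slow_wave = {
      freq <- stats::runif(1, 0.5, 2)
      hann <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
      amp * sqrt(2) * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi)) * hann
    },
    eye_movement = amp * sqrt(2) * sample(c(-1, 1), 1) * sin(pi * t / dur))
}

#' Simulate one stage-labeled 30-s epoch
#'
#' Builds the two near-symmetric frontopolar channels: dominant rhythm
#' (windowed by its occupancy envelope), background carriers, 1/f noise and
#' transient events are shared between channels; white sensor noise is
#' independent per channel; eye-movement deflections enter the two channels
#' with opposite sign. Uses R's current RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param recipe a [stage_recipe()].
#' @param sample_rate_hz sampling rate in Hz.
#' @param epoch_duration_s epoch length in seconds.
#' @param channel_names names of the two output channels.
#' @return An [epoch_signal()].
#' @export
simulate_epoch <- function(recipe, sample_rate_hz = 128,
                           epoch_duration_s = 30,
                           channel_names = c("FP1", "FP2")) {
  stopifnot(inherits(recipe, "stage_recipe"))
  fs <- sample_rate_hz
  n <- round(epoch_duration_s * fs)
  jit <- function() exp(stats::rnorm(1, 0, recipe$amp_jitter_sd))
  occ_rng <- recipe$dominant$occupancy
  if (length(occ_rng) == 1) occ_rng <- rep(occ_rng, 2)
  occ <- stats::runif(1, occ_rng[1], occ_rng[2])
  shared <- recipe$dominant$amp * jit() *
    occupancy_envelope(n, fs, occ) *
    band_noise(n, fs, recipe$dominant$band)
  for (bg in recipe$background)
    shared <- shared + bg$amp * jit() * band_noise(n, fs, bg$band)
  shared <- shared + recipe$pink_amp * jit() * pink_noise(n, fs)
  anti <- numeric(n)          # anti-correlated across channels
  for (ev in recipe$events) {
    n_ev <- stats::rpois(1, ev$rate)
    for (i in seq_len(n_ev)) {
      dur <- stats::runif(1, ev$dur[1], ev$dur[2])
      if (dur >= epoch_duration_s)
        stop("event duration exceeds the epoch length")
      wf <- event_waveform(ev$type, dur, ev$amp, fs)
      start <- sample.int(n - length(wf) + 1L, 1L)
      sel <- start:(start + length(wf) - 1L)
      if (ev$type == "eye_movement") anti[sel] <- anti[sel] + wf
      else shared[sel] <- shared[sel] + wf
    }
  }
  ch1 <- shared + anti + recipe$white_amp * stats::rnorm(n)
  ch2 <- shared - anti + recipe$white_amp * stats::rnorm(n)
  out <- list(ch1, ch2)
  names(out) <- channel_names
  epoch_signal(out, fs, epoch_index = 0L,
               epoch_duration_s = epoch_duration_s)
}

# fixed master-seed -> per-subject substream derivation (documented so
# cohorts are stable across platforms): both constants are primes
subject_seed <- function(master_seed, subject_index) {
  as.integer((as.numeric(master_seed) * 48271 +
                as.numeric(subject_index) * 104729) %% 2147483647)
}

#' Simulate one subject's night
#'
#' Draws a stage sequence from the configured prevalence, applies the
#' subject's multiplicative amplitude jitter to every recipe amplitude
#' (a global gain, as produced by electrode and skull differences), and
#' concatenates the simulated epochs into a continuous recording.
#'
#' @param config a [simulation_config()].
#' @param subject_index 1-based subject number; the RNG substream is
#'   derived from `config$seed` and this index.
#' @return List with elements `recording` (an [eeg_recording()]) and
#'   `hypnogram` (a [hypnogram()]).
#' @export
simulate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(subject_seed(config$seed, subject_index))
  gain <- exp(stats::rnorm(1, 0, config$jitter_sd))
  recipes <- lapply(config$recipes, function(r) {
    r$dominant$amp <- r$dominant$amp * gain
    r$background <- lapply(r$background, function(b) {
      b$amp <- b$amp * gain; b })
    r$events <- lapply(r$events, function(e) { e$amp <- e$amp * gain; e })
    r$pink_amp <- r$pink_amp * gain
    r$white_amp <- r$white_amp * gain
    r
  })
  stages <- sample(SLEEP_STAGES, config$epochs_per_subject, replace = TRUE,
                   prob = config$stage_prevalence)
  fs <- config$sample_rate_hz
  eps <- lapply(stages, function(s)
    simulate_epoch(recipes[[s]], sample_rate_hz = fs))
  sig <- list(
    FP1 = unlist(lapply(eps, function(e) e$channels[[1]]), use.names = FALSE),
    FP2 = unlist(lapply(eps, function(e) e$channels[[2]]), use.names = FALSE))
  list(recording = eeg_recording(sig, fs,
                                 subject_id = sprintf("S%02d", subject_index)),
       hypnogram = hypnogram(stages))
}

#' Simulate a multi-subject cohort
#'
#' Each subject uses an independent RNG substream derived from the master
#' seed, so regenerating with the same seed reproduces the cohort exactly
#' and adding subjects never perturbs earlier ones.
#'
#' @param config a [simulation_config()] with `n_subjects >= 2`.
#' @param dir optional directory: when given, each subject is written as
#'   `<id>.edf` plus `<id>.hyp.csv` and a `manifest.json` (seed, files,
#'   prevalence) is emitted.
#' @param physical_range EDF physical range (uV) used when writing.
#' @return Invisibly, a list of `list(recording=, hypnogram=)` per subject;
#'   with `dir`, the manifest path is attached as attribute `"manifest"`.
#' @export
simulate_cohort <- function(config, dir = NULL,
                            physical_range = c(-1000, 1000)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_subjects < 2) stop("`n_subjects` must be >= 2")
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) simulate_subject(config, i))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- lapply(subjects, function(s) {
      id <- s$recording$subject_id
      edf <- file.path(dir, paste0(id, ".edf"))
      hyp <- file.path(dir, paste0(id, ".hyp.csv"))
      write_edf(s$recording, edf, physical_range = physical_range)
      write_hypnogram(s$hypnogram, hyp)
      list(subject_id = id, edf = basename(edf), hypnogram = basename(hyp))
    })
    manifest <- file.path(dir, "manifest.json")
    jsonlite::write_json(
      list(seed = config$seed, n_subjects = config$n_subjects,
           epochs_per_subject = config$epochs_per_subject,
           sample_rate_hz = config$sample_rate_hz,
           stage_prevalence = as.list(config$stage_prevalence),
           subjects = files),
      manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    attr(subjects, "manifest") <- manifest
  }
  invisible(subjects)
}
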
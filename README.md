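# sleepstager

Automatic sleep-stage classification from the two forehead EEG channels
FP1 and FP2.

Overnight polysomnography is the clinical reference for staging sleep, but
it needs a laboratory, a technician and a dozen electrodes. The frontopolar
(forehead) sites are hairless, so a self-applied headband can record them at
home — if the staging algorithm can live with just those two channels. This
package implements such a system for R users working with sleep EEG:

1. **Preprocessing** — each 30-s epoch (the AASM scoring unit; 3840 samples
   per channel at 128 Hz) is band-pass filtered to 0.5–50 Hz
   (Butterworth high-pass/low-pass cascade, zero phase).
2. **Knowledge-based feature extraction** — a short-time Fourier transform
   with a 1-s Hamming window and 0.5-s step turns the epoch into 59
   per-segment spectra; each segment is normalized by its total power
   (removing inter-individual gain); band-power series for
   lower delta (1–2 Hz), delta (1–4), theta (5–7), alpha (8–12),
   sigma (12–14), beta (15–30) and gamma (30–50 Hz) are summarized into 13
   statistics per channel that mirror how experts score visually: sorted
   upper/lower-fraction means for sustained rhythms (alpha/theta/beta at
   50%, lower delta at 80%), segment max + remaining-mean for transients
   (spindles in sigma, K-complexes in delta), and the overall gamma mean.
   A conventional baseline (one whole-epoch periodogram, 50 one-Hz bands
   per channel) is provided for comparison.
3. **Classification** — a from-scratch relevance vector machine (sparse
   Bayesian kernel classifier, logistic likelihood with Laplace
   approximation, evidence-based hyperparameter updates
   `alpha_i <- gamma_i / mu_i^2`), wrapped one-against-all over the five
   stages W/N1/N2/N3/REM. LDA, k-NN (k = 13) and an external SVM
   (cost = 50) sit behind the same interface.
4. **Evaluation** — leave-one-subject-out cross-validation with overall
   accuracy, per-stage sensitivity, Cohen's kappa, pooled confusion
   matrices, Fisher separability criteria `J1 = tr(S_b)/tr(S_w)` and
   `J2 = tr(S_w^-1 S_b)`, and a 2-component PCA projection for scatter
   plots.
5. **Synthetic data** — a seeded simulator produces stage-labeled
   two-channel EEG whose spectral structure follows the AASM rules
   (alpha-dominant W, theta-dominant N1, spindles/K-complexes in N2,
   high-amplitude slow waves in N3, theta plus anti-correlated eye
   movements in REM), so the whole pipeline can be exercised and tested
   without clinical recordings.

EDF (16-bit European Data Format) reading/writing and a plain-text
hypnogram side-car format (`epoch,stage` CSV; `?` = unscored) are built in.

## Worked example

```r
library(sleepstager)

# a small synthetic cohort: 4 subjects, 40 epochs each
cfg    <- simulation_config(n_subjects = 4, epochs_per_subject = 40, seed = 7)
cohort <- simulate_cohort(cfg)

# features for every subject (filter + STFT + band statistics)
features <- do.call(rbind, lapply(cohort, function(s)
  feature_table(segment_epochs(s$recording, s$hypnogram),
                s$recording$subject_id, mode = "knowledge")))

# separability of the feature set (z-scored, as the classifier sees it)
feature_separability(features)
#> <fisher_scores> J1 = 0.9391, J2 = 21.95

# leave-one-subject-out evaluation with the RVM
report <- loso_evaluate(features, classifier_spec("rvm"))
report
#> <evaluation_report> rvm, 4 subject(s)
#>   accuracy 83.1 +/- 10.5 %   kappa 0.76 +/- 0.16  (mean +/- SD across subjects)
#>   pooled: accuracy 83.1 %, kappa 0.77 over 160 epochs
report$pooled_confusion
#>      predicted
#> truth  W N1 N2 N3 REM
#>   W   29  0  0  0   0
#>   N1   0 10  6  0   0
#>   N2   0  7 57  6   3
#>   N3   0  0  3 16   0
#>   REM  0  0  2  0  21
```

`J1`/`J2` are scatter-matrix ratios — larger means the five stages are
further apart in feature space relative to their spread. The report gives
per-subject and pooled agreement between predicted and true hypnograms;
kappa corrects the agreement for chance given the stage marginals. Most
confusion involves N1, whose EEG resembles N2 and REM — the hard stage for
any EEG-only system. A command-line front end
(`inst/cli/sleepstager.R`) exposes `simulate`, `extract`, `train`,
`predict` and `evaluate-loso` subcommands over the same functions.

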
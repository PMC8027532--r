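# Shared configuration for the analysis workflow. Each numbered script
# sources this file; the cohort is regenerated deterministically from the
# master seed wherever a stage needs raw signals, so no bulky
# intermediate files are kept.

library(eegcomplexity)

MASTER_SEED <- 20250915

# Two age groups differing in broadband irregularity (higher fine-scale
# entropy in the older group) and in spectral exponent (flatter 1/f in
# the older group) -- the two effects the pipeline is built to detect and
# dissociate. Desk-scale sizes: 16 channels at 128 Hz, 40 s per subject.
COHORT <- cohort_spec(
  groups = list(
    cohort_group("age9", 12, beta_mean = 1.8, beta_sd = 0.2,
                 irregularity_mix = 0.10, alpha_amp = 0.5),
    cohort_group("age15", 12, beta_mean = 1.5, beta_sd = 0.2,
                 irregularity_mix = 0.45, alpha_amp = 0.5)),
  n_channels = 16, fs = 128, duration_s = 40, seed = MASTER_SEED)

MSE_PARAMS <- mse_params(m = 2, r_frac = 0.5, scales = 1:20)
WELCH <- list(win_len = 256, overlap_frac = 0.5, fmin = 1, fmax = 30)
TFCE <- list(E = 0.66, H = 2, n_perm = 1000, alpha = 0.05)
EPOCH_LEN_S <- 20
LOWPASS_HZ <- 30

RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

make_cohort <- function() generate_cohort(COHORT)

preprocess_cohort <- function(coh) {
  lapply(coh$recordings, preprocess, lowpass_hz = LOWPASS_HZ,
         epoch_len_s = EPOCH_LEN_S)
}
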
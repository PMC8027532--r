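#' Specify a synthetic EEG cohort
#'
#' The generator stands in for an unavailable developmental resting-state
#' cohort: multi-channel colored-noise EEG with subject-specific spectral
#' exponents, an alpha-band oscillatory component, and group-dependent
#' differences in broadband irregularity (white-noise admixture raising
#' entropy) and in spectral exponent (flatter 1/f with "older" groups).
#' The two effects are independently controllable so entropy changes can be
#' dissociated from spectral-slope changes.
#'
#' @param groups list of group definitions from [cohort_group()].
#' @param n_channels number of EEG channels.
#' @param fs sampling rate in Hz (default 512, dense-array resting EEG).
#' @param duration_s recorded duration per subject in seconds (default 60,
#'   one resting block; must cover at least one 20-s analysis epoch).
#' @param effect_channels integer indices of channels carrying the
#'   group-specific parameters; other channels use the first (reference)
#'   group's parameters for every subject. `NULL` = all channels.
#' @param seed master seed; all per-subject seeds derive from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, n_channels = 96, fs = 512, duration_s = 60,
                        effect_channels = NULL, seed = 1L) {
  stopifnot(length(groups) >= 1, n_channels >= 1, fs > 0)
  if (duration_s < 20)
    stop("duration_s must be >= 20 (one full analysis epoch)")
  groups <- lapply(groups, function(g) {
    g$n_subjects <- as.integer(g$n_subjects)
    g
  })
  labs <- vapply(groups, `[[`, character(1), "label")
  if (anyDuplicated(labs)) stop("duplicate group labels")
  for (g in groups) {
    if (g$n_subjects < 2) stop("n_subjects must be >= 2 per group")
    if (g$irregularity_mix < 0 || g$irregularity_mix > 1)
      stop("irregularity_mix must be in [0, 1]")
  }
  if (!is.null(effect_channels)) {
    effect_channels <- as.integer(effect_channels)
    if (any(effect_channels < 1 | effect_channels > n_channels))
      stop("effect_channels out of range")
  }
  structure(list(groups = groups, n_channels = n_channels, fs = fs,
                 duration_s = duration_s, effect_channels = effect_channels,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Define one synthetic group
#'
#' @param label group label (e.g. an age-group name).
#' @param n_subjects subjects in the group (>= 2).
#' @param beta_mean,beta_sd mean and SD of the subject-level spectral
#'   exponent beta (PSD ~ 1/f^beta), truncated to \[0, 3\].
#' @param irregularity_mix fraction in \[0, 1\] of white-noise admixture;
#'   larger values raise fine-scale sample entropy.
#' @param alpha_amp amplitude of the alpha sinusoid relative to the
#'   unit-variance broadband background.
#' @param alpha_freq_hz alpha frequency (default 10 Hz).
#' @return A list usable in [cohort_spec()].
#' @export
cohort_group <- function(label, n_subjects, beta_mean = 1.5, beta_sd = 0.2,
                         irregularity_mix = 0, alpha_amp = 0.5,
                         alpha_freq_hz = 10) {
  list(label = label, n_subjects = as.integer(n_subjects),
       beta_mean = beta_mean, beta_sd = beta_sd,
       irregularity_mix = irregularity_mix, alpha_amp = alpha_amp,
       alpha_freq_hz = alpha_freq_hz)
}

#' Colored (1/f^beta) noise by spectral synthesis
#'
#' White-noise Fourier amplitudes are scaled by `f^(-beta/2)` with uniform
#' random phases and inverse-transformed, giving exact control of the
#' expected power-law exponent. Output is standardized to zero mean, unit
#' variance.
#'
#' @param beta spectral exponent in \[0, 3\]; 0 = white, 1 = pink,
#'   2 = brown.
#' @param n number of samples (>= 2).
#' @param fs sampling rate in Hz (sets the frequency grid only).
#' @param seed optional integer seed; identical seeds give identical
#'   signals.
#' @return Numeric vector of length `n`.
#' @export
colored_noise <- function(beta, n, fs = 512, seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  stopifnot(beta >= 0, beta <= 3)
  if (!is.null(seed)) set.seed(seed)
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- f^(-beta / 2)
  ph <- runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  if (n %% 2 == 0) {
    spec[nf] <- complex(modulus = amp[nf], argument = 0)  # Nyquist bin real
    full[2:(nf + 1)] <- spec
    if (nf > 1) full[(nf + 2):n] <- Conj(spec[(nf - 1):1])
  } else {
    full[2:(nf + 1)] <- spec
    full[(nf + 2):n] <- Conj(spec[nf:1])
  }
  x <- Re(fft(full, inverse = TRUE))
  (x - mean(x)) / sd(x)
}

#' Generate one synthetic subject
#'
#' Each channel is a standardized mixture
#' `(1 - mix) * colored_noise(beta_subject) + mix * white noise` plus an
#' alpha sinusoid with random phase, scaled to a µV-like amplitude.
#' `beta_subject ~ Normal(beta_mean, beta_sd)` truncated to \[0, 3\].
#' Group-specific parameters apply on `effect_channels` only; remaining
#' channels use the reference (first) group's parameters.
#'
#' @param spec a [cohort_spec()].
#' @param group group label present in `spec`.
#' @param subject_seed integer seed for this subject.
#' @param subject_id subject identifier.
#' @param condition recording condition.
#' @param montage optional `eeg_montage` (default [default_montage()] with
#'   `spec$n_channels` channels).
#' @return An `eeg_recording`.
#' @export
generate_subject <- function(spec, group, subject_seed,
                             subject_id = paste0(group, "_", subject_seed),
                             condition = "eyes_closed", montage = NULL) {
  labs <- vapply(spec$groups, `[[`, character(1), "label")
  gi <- match(group, labs)
  if (is.na(gi)) stop("unknown group: ", group)
  if (is.null(montage)) montage <- default_montage(spec$n_channels)
  set.seed(as.integer(subject_seed))
  n <- round(spec$duration_s * spec$fs)
  eff <- spec$effect_channels
  if (is.null(eff)) eff <- seq_len(spec$n_channels)
  g_eff <- spec$groups[[gi]]
  g_ref <- spec$groups[[1]]
  beta_eff <- rnorm_trunc(g_eff$beta_mean, g_eff$beta_sd, 0, 3)
  beta_ref <- rnorm_trunc(g_ref$beta_mean, g_ref$beta_sd, 0, 3)
  tgrid <- (seq_len(n) - 1) / spec$fs
  dat <- matrix(0, spec$n_channels, n)
  for (ch in seq_len(spec$n_channels)) {
    g <- if (ch %in% eff) g_eff else g_ref
    beta <- if (ch %in% eff) beta_eff else beta_ref
    mix <- g$irregularity_mix
    x <- (1 - mix) * colored_noise(beta, n, spec$fs) + mix * rnorm(n)
    x <- (x - mean(x)) / sd(x)
    x <- x + g$alpha_amp * sin(2 * pi * g$alpha_freq_hz * tgrid +
                                 runif(1, 0, 2 * pi))
    dat[ch, ] <- 10 * x  # ~10 µV RMS broadband, EEG-like amplitude
  }
  recording(dat, spec$fs, montage, subject_id = subject_id,
            condition = condition, group = group)
}

rnorm_trunc <- function(mean, sd, lo, hi) {
  if (sd == 0) return(min(max(mean, lo), hi))
  for (i in 1:1000) {
    v <- rnorm(1, mean, sd)
    if (v >= lo && v <= hi) return(v)
  }
  min(max(mean, lo), hi)
}

#' Generate a full synthetic cohort
#'
#' Per-subject seeds are drawn reproducibly from the master seed, so the
#' same `spec` always yields a byte-identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @param condition recording condition for all subjects.
#' @return List with `recordings` (list of `eeg_recording`), `manifest`
#'   (data.frame: subject_id, group, seed), and `montage`.
#' @export
generate_cohort <- function(spec, condition = "eyes_closed") {
  montage <- default_montage(spec$n_channels)
  labs <- vapply(spec$groups, `[[`, character(1), "label")
  ns <- vapply(spec$groups, `[[`, integer(1), "n_subjects")
  total <- sum(ns)
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  group_of <- rep(labs, ns)
  ids <- sprintf("%s_%02d", group_of, unlist(lapply(ns, seq_len)))
  recs <- vector("list", total)
  for (i in seq_len(total)) {
    recs[[i]] <- generate_subject(spec, group_of[i], seeds[i],
                                  subject_id = ids[i],
                                  condition = condition, montage = montage)
  }
  list(recordings = recs,
       manifest = data.frame(subject_id = ids, group = group_of,
                             seed = seeds),
       montage = montage)
}
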
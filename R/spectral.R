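#' Welch power spectral density
#'
#' Averaged modified periodogram: Hanning-tapered windows of `win_len`
#' samples with `overlap_frac` overlap, each mean-removed, one-sided PSD
#' normalized by the window power, averaged across windows, restricted to
#' `[fmin, fmax]`.
#'
#' @param x numeric signal, at least `win_len` samples.
#' @param fs sampling rate in Hz.
#' @param win_len window length in samples (default 1024; at 512 Hz this
#'   is a 2-s window).
#' @param overlap_frac fractional overlap between windows (default 0.5).
#' @param fmin,fmax retained frequency band in Hz (defaults 1 and 30).
#' @return List with `freqs` (Hz) and `power` (linear units, per Hz).
#' @export
welch_psd <- function(x, fs, win_len = 1024, overlap_frac = 0.5,
                      fmin = 1, fmax = 30) {
  n <- length(x)
  if (n < win_len) stop("signal shorter than one Welch window")
  hop <- max(1L, round(win_len * (1 - overlap_frac)))
  starts <- seq(1L, n - win_len + 1L, by = hop)
  k <- 0:(win_len - 1)
  w <- 0.5 - 0.5 * cos(2 * pi * k / (win_len - 1))  # Hanning taper
  u <- sum(w^2)
  half <- win_len %/% 2 + 1L
  acc <- numeric(half)
  for (s0 in starts) {
    seg <- x[s0:(s0 + win_len - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg)[seq_len(half)])^2 / (fs * u)
    p[2:(half - 1L)] <- 2 * p[2:(half - 1L)]  # one-sided
    acc <- acc + p
  }
  pw <- acc / length(starts)
  f <- (seq_len(half) - 1L) * fs / win_len
  keep <- f >= fmin & f <= fmax
  list(freqs = f[keep], power = pw[keep])
}

#' Power-law exponent by robust log-log regression
#'
#' Iteratively reweighted least squares (Tukey bisquare, conventional
#' tuning constant, up to 50 iterations) of log10 power on log10
#' frequency; the returned slope is the 1/f exponent (so an exact
#' `power = f^-2` spectrum gives slope -2). If IRLS fails to converge the
#' fit falls back to ordinary least squares with a warning.
#'
#' @param freqs frequency grid in Hz.
#' @param power spectral power, linear units (or dB with `db = TRUE`);
#'   must be positive on the fitted band.
#' @param f_lo,f_hi fitted band limits in Hz (defaults 1 and 30).
#' @param db set `TRUE` if `power` is in dB (10 log10).
#' @return List with `slope`, `intercept` (log10 power at log10 f = 0),
#'   `converged`, and `min_weight` (smallest IRLS weight, a robustness
#'   diagnostic).
#' @export
loglog_slope <- function(freqs, power, f_lo = 1, f_hi = 30, db = FALSE) {
  keep <- freqs >= f_lo & freqs <= f_hi & freqs > 0
  if (sum(keep) < 5)
    stop("need at least 5 frequency bins in the fitted band")
  p <- power[keep]
  if (db) p <- 10^(p / 10)
  if (any(p <= 0)) stop("power must be positive on the fitted band")
  lx <- log10(freqs[keep])
  ly <- log10(p)
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(ly ~ lx, psi = MASS::psi.bisquare,
                               maxit = 50)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    warning("robust fit did not converge; falling back to least squares")
    fit <- stats::lm(ly ~ lx)
    co <- stats::coef(fit)
    return(list(slope = unname(co[2]), intercept = unname(co[1]),
                converged = FALSE, min_weight = 1))
  }
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       converged = TRUE, min_weight = min(fit$w))
}

#' Per-subject PSD and power-law slope maps
#'
#' Welch PSD per channel, averaged over retained epochs (each epoch is a
#' continuous segment, so windows never straddle epoch boundaries), plus
#' per-channel and per-region power-law exponents. Region slopes are, by
#' default, fit on the region-averaged (linear) spectrum; set
#' `region_mode = "mean_of_slopes"` to average channel slopes instead.
#'
#' @param es an `epoch_set`; conventionally the eyes-closed condition.
#' @param win_len,overlap_frac,fmin,fmax Welch parameters (see
#'   [welch_psd()]).
#' @param region_mode `"spectrum_then_fit"` (default) or
#'   `"mean_of_slopes"`.
#' @return List of two maps: `psd` (a `psd_map` with `values` = channel x
#'   frequency dB matrix and `freqs`) and `slope` (a `slope_map` with
#'   per-channel `slope`, `intercept`, `min_weight`, and per-region
#'   `region_slope`).
#' @export
subject_spectra <- function(es, win_len = 1024, overlap_frac = 0.5,
                            fmin = 1, fmax = 30,
                            region_mode = c("spectrum_then_fit",
                                            "mean_of_slopes")) {
  region_mode <- match.arg(region_mode)
  eps <- retained_epochs(es)
  n_ch <- dim(es$epochs)[2]
  p_acc <- NULL
  for (ep in eps) {
    for (ch in seq_len(n_ch)) {
      ps <- welch_psd(ep[ch, ], es$fs, win_len, overlap_frac, fmin, fmax)
      if (is.null(p_acc)) {
        freqs <- ps$freqs
        p_acc <- matrix(0, n_ch, length(freqs))
      }
      p_acc[ch, ] <- p_acc[ch, ] + ps$power
    }
  }
  p_lin <- p_acc / length(eps)
  floor_p <- .Machine$double.eps
  p_db <- 10 * log10(pmax(p_lin, floor_p))
  dimnames(p_db) <- list(es$montage$labels, sprintf("f%.3g", freqs))

  fits <- lapply(seq_len(n_ch), function(ch)
    loglog_slope(freqs, p_lin[ch, ], fmin, fmax))
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  names(slope) <- es$montage$labels

  regions <- levels(droplevels(es$montage$region))
  region_slope <- vapply(regions, function(rg) {
    chs <- which(es$montage$region == rg)
    if (region_mode == "spectrum_then_fit") {
      loglog_slope(freqs, colMeans(p_lin[chs, , drop = FALSE]),
                   fmin, fmax)$slope
    } else {
      mean(slope[chs])
    }
  }, numeric(1))

  psd <- structure(list(subject_id = es$subject_id, group = es$group,
                        values = p_db, freqs = freqs,
                        params = list(win_len = win_len,
                                      overlap_frac = overlap_frac,
                                      fmin = fmin, fmax = fmax,
                                      taper = "hanning")),
                   class = "psd_map")
  slp <- structure(list(subject_id = es$subject_id, group = es$group,
                        slope = slope,
                        intercept = vapply(fits, `[[`, numeric(1),
                                           "intercept"),
                        min_weight = vapply(fits, `[[`, numeric(1),
                                            "min_weight"),
                        region_slope = region_slope,
                        region_mode = region_mode),
                   class = "slope_map")
  list(psd = psd, slope = slp)
}

#' @export
print.psd_map <- function(x, ...) {
  cat(sprintf("<psd_map> %s [%s]: %d ch x %d freq bins (%g-%g Hz)\n",
              x$subject_id, x$group, nrow(x$values), ncol(x$values),
              min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' @export
print.slope_map <- function(x, ...) {
  cat(sprintf("<slope_map> %s [%s]: mean channel slope %.3f\n",
              x$subject_id, x$group, mean(x$slope)))
  invisible(x)
}
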
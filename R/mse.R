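#' Multiscale entropy parameters
#'
#' @param m template (pattern) length; default 2.
#' @param r_frac match tolerance as a fraction of the signal SD; default
#'   0.5.
#' @param scales integer coarse-graining factors, strictly increasing;
#'   default 1:20.
#' @param r_mode how the absolute tolerance is resolved per scale:
#'   `"sd_scale1"` (default, the original multiscale-entropy convention:
#'   `r_frac` x SD of the scale-1 signal, held fixed across scales),
#'   `"sd_per_scale"` (re-anchored to each coarse-grained series' SD), or
#'   `"absolute"` (`r_frac` used directly as an absolute tolerance).
#' @return An `mse_params` list.
#' @export
mse_params <- function(m = 2, r_frac = 0.5, scales = 1:20,
                       r_mode = c("sd_scale1", "sd_per_scale", "absolute")) {
  r_mode <- match.arg(r_mode)
  stopifnot(m >= 1, r_frac > 0, length(scales) >= 1)
  scales <- as.integer(scales)
  if (any(scales < 1) || is.unsorted(scales, strictly = TRUE))
    stop("scales must be strictly increasing positive integers")
  structure(list(m = as.integer(m), r_frac = r_frac, scales = scales,
                 r_mode = r_mode), class = "mse_params")
}

#' Coarse-grain a signal
#'
#' Replaces non-overlapping windows of length `tau` by their means,
#' producing the scale-`tau` series of length `floor(N / tau)`.
#'
#' @param x numeric signal.
#' @param tau integer scale factor (>= 1, <= length(x)).
#' @return Numeric vector of length `floor(length(x) / tau)`.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1) stop("tau must be >= 1")
  n <- length(x)
  if (tau > n) stop("tau exceeds the signal length")
  if (tau == 1L) return(x)
  nb <- n %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' SampEn(m, r, N) = -ln(B / A) where A counts pairs of distinct m-length
#' templates within Chebyshev distance < `r_abs` and B the corresponding
#' (m+1)-length matches; both template sets start at the same N - m
#' positions so the counts are comparable, and self-matches are excluded.
#' Low values indicate a regular, predictable signal.
#'
#' @param x numeric signal with `length(x) > m + 1`, all finite.
#' @param m template length (default 2).
#' @param r_abs absolute match tolerance (> 0).
#' @return Entropy in nats, or `NA` (undefined) when either template count
#'   is zero. Never silently 0 for unmatched series.
#' @export
sample_entropy <- function(x, m = 2, r_abs) {
  m <- as.integer(m)
  if (!all(is.finite(x))) stop("signal contains non-finite values")
  if (length(x) <= m + 1) stop("series too short for template length m")
  stopifnot(r_abs > 0)
  ab <- sampen_counts_cpp(as.numeric(x), m, r_abs)
  if (ab[1] == 0 || ab[2] == 0) return(NA_real_)
  -log(ab[2] / ab[1])
}

#' Multiscale entropy curve for one signal
#'
#' Coarse-grains at each scale factor and computes sample entropy with the
#' tolerance resolved per `params$r_mode`. Undefined entries (no template
#' matches) propagate as `NA` without aborting the curve.
#'
#' @param x numeric signal.
#' @param params an [mse_params()].
#' @return Named numeric vector, one entropy per scale.
#' @export
mse_curve <- function(x, params = mse_params()) {
  n <- length(x)
  if (n %/% max(params$scales) <= params$m + 1)
    stop("signal too short for the coarsest scale")
  r1 <- switch(params$r_mode,
               sd_scale1 = params$r_frac * sd(x),
               absolute = params$r_frac,
               NA_real_)
  out <- vapply(params$scales, function(tau) {
    xs <- coarse_grain(x, tau)
    r_abs <- if (params$r_mode == "sd_per_scale")
      params$r_frac * sd(xs) else r1
    if (!is.finite(r_abs) || r_abs <= 0) return(NA_real_)
    sample_entropy(xs, params$m, r_abs)
  }, numeric(1))
  names(out) <- paste0("scale", params$scales)
  out
}

#' Per-subject multiscale entropy map
#'
#' Computes the channel x scale entropy matrix on every retained epoch and
#' averages across epochs, ignoring undefined (NA) entries.
#'
#' @param es an `epoch_set` with at least one retained epoch.
#' @param params an [mse_params()].
#' @return An `mse_map`: list with `subject_id`, `group`, `values`
#'   (channel x scale matrix, nats), `scales`, `n_epochs_used`,
#'   `n_undefined` (count of undefined epoch-level entries), `params`.
#' @export
subject_mse <- function(es, params = mse_params()) {
  eps <- retained_epochs(es)
  n_ch <- dim(es$epochs)[2]
  n_sc <- length(params$scales)
  acc <- matrix(0, n_ch, n_sc)
  cnt <- matrix(0L, n_ch, n_sc)
  for (ep in eps) {
    for (ch in seq_len(n_ch)) {
      v <- mse_curve(ep[ch, ], params)
      ok <- !is.na(v)
      acc[ch, ok] <- acc[ch, ok] + v[ok]
      cnt[ch, ok] <- cnt[ch, ok] + 1L
    }
  }
  vals <- acc / cnt
  vals[cnt == 0L] <- NA_real_
  dimnames(vals) <- list(es$montage$labels,
                         paste0("scale", params$scales))
  structure(list(subject_id = es$subject_id, group = es$group,
                 values = vals, scales = params$scales,
                 n_epochs_used = length(eps),
                 n_undefined = sum(cnt < length(eps)),
                 params = params),
            class = "mse_map")
}

#' @export
print.mse_map <- function(x, ...) {
  cat(sprintf("<mse_map> %s [%s]: %d ch x %d scales, %d epoch(s)\n",
              x$subject_id, x$group, nrow(x$values), ncol(x$values),
              x$n_epochs_used))
  invisible(x)
}
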
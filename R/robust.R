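#' Trimmed mean
#'
#' Sorts the values, drops `floor(trim * n)` observations from each end,
#' and averages the remainder.
#'
#' @param x numeric values.
#' @param trim fraction trimmed from each end (default 0.2).
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(x, trim = 0.2) {
  x <- x[!is.na(x)]
  n <- length(x)
  g <- floor(trim * n)
  if (n - 2 * g < 1) stop("all values would be trimmed")
  mean(sort(x)[(g + 1):(n - g)])
}

#' Region x Hemisphere cell means from subject MSE maps
#'
#' Averages each subject's entropy over the requested scales and over the
#' channels in each of the six {frontal, central, parieto-occipital} x
#' {left, right} cells. Midline and unassigned channels are excluded from
#' the lateralized cells.
#'
#' @param mse_maps list of `mse_map` objects.
#' @param montage the shared `eeg_montage`.
#' @param scales scales averaged over (`NULL` = all).
#' @return data.frame, one row per subject: `subject_id`, `group`, and six
#'   cell columns `frontal_left`, ..., `parieto_occipital_right`.
#' @export
region_hemisphere_cells <- function(mse_maps, montage, scales = NULL) {
  regions <- c("frontal", "central", "parieto_occipital")
  hemis <- c("left", "right")
  rows <- lapply(mse_maps, function(m) {
    sc <- if (is.null(scales)) seq_len(ncol(m$values))
          else match(scales, m$scales)
    v <- rowMeans(m$values[, sc, drop = FALSE], na.rm = TRUE)
    cells <- unlist(lapply(regions, function(rg)
      vapply(hemis, function(hm)
        mean(v[montage$region == rg & montage$hemisphere == hm],
             na.rm = TRUE), numeric(1))))
    names(cells) <- paste(rep(regions, each = 2), hemis, sep = "_")
    data.frame(subject_id = m$subject_id, group = m$group,
               as.list(cells), check.names = FALSE)
  })
  do.call(rbind, rows)
}

ww_contrasts <- function(cells) {
  f <- (cells$frontal_left + cells$frontal_right) / 2
  c_ <- (cells$central_left + cells$central_right) / 2
  po <- (cells$parieto_occipital_left + cells$parieto_occipital_right) / 2
  dl <- list(
    region_frontal_vs_central = f - c_,
    region_frontal_vs_parieto_occipital = f - po,
    region_central_vs_parieto_occipital = c_ - po,
    hemisphere_left_vs_right =
      (cells$frontal_left + cells$central_left +
         cells$parieto_occipital_left) / 3 -
      (cells$frontal_right + cells$central_right +
         cells$parieto_occipital_right) / 3,
    interaction_frontal_vs_central =
      (cells$frontal_left - cells$frontal_right) -
      (cells$central_left - cells$central_right),
    interaction_frontal_vs_parieto_occipital =
      (cells$frontal_left - cells$frontal_right) -
      (cells$parieto_occipital_left - cells$parieto_occipital_right),
    interaction_central_vs_parieto_occipital =
      (cells$central_left - cells$central_right) -
      (cells$parieto_occipital_left - cells$parieto_occipital_right))
  dl
}

#' Percentile-bootstrap trimmed-mean contrasts (within-within design)
#'
#' For the Region x Hemisphere topography design, computes per-subject
#' linear contrast scores — pairwise region differences averaged over
#' hemisphere, the hemisphere difference averaged over region, and
#' interaction (difference-of-differences) contrasts between region
#' pairs — and for each: the trimmed-mean estimate, a percentile
#' bootstrap CI from resampling subjects with replacement, and the
#' two-sided bootstrap p-value
#' `p = 2 * min(P*(theta* > 0), P*(theta* < 0))` with the half-count tie
#' adjustment.
#'
#' @param cells data.frame from [region_hemisphere_cells()] (>= 10
#'   subjects with six finite cells).
#' @param n_boot bootstrap resamples (default 2000).
#' @param trim trimming fraction (default 0.2).
#' @param conf CI level (default 0.95).
#' @param seed integer seed.
#' @return data.frame, one row per contrast: `contrast`, `estimate`,
#'   `lower`, `upper`, `p`, `n_boot`, `seed`.
#' @export
ww_trimmed_bootstrap <- function(cells, n_boot = 2000, trim = 0.2,
                                 conf = 0.95, seed = 1) {
  need <- c("frontal_left", "frontal_right", "central_left",
            "central_right", "parieto_occipital_left",
            "parieto_occipital_right")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("missing cell column(s): ",
                         paste(miss, collapse = ", "))
  ok <- complete.cases(cells[need])
  cells <- cells[ok, , drop = FALSE]
  n <- nrow(cells)
  if (n < 10) stop("need at least 10 subjects with complete cells")
  scores <- ww_contrasts(cells)
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  if (any(apply(idx, 1, function(i) length(unique(i)) == 1L)))
    warning("degenerate bootstrap resample(s) (all-identical subjects)")
  lo_q <- (1 - conf) / 2
  rows <- lapply(names(scores), function(nm) {
    sc <- scores[[nm]]
    est <- trimmed_mean(sc, trim)
    boot <- apply(idx, 1, function(i) trimmed_mean(sc[i], trim))
    ci <- unname(quantile(boot, c(lo_q, 1 - lo_q), type = 6))
    p_gt <- (sum(boot > 0) + 0.5 * sum(boot == 0)) / n_boot
    p <- max(2 * min(p_gt, 1 - p_gt), 1 / n_boot)
    data.frame(contrast = nm, estimate = est, lower = ci[1],
               upper = ci[2], p = min(p, 1), n_boot = n_boot, seed = seed)
  })
  do.call(rbind, rows)
}

#' Robust linear fit (IRLS bisquare)
#'
#' Tukey-bisquare iteratively reweighted least squares, the same machinery
#' used for the spectral power-law fits. `variance_explained` is the
#' squared correlation between fitted and observed responses.
#'
#' @param x predictor values.
#' @param y response values.
#' @return List with `slope`, `intercept`, `variance_explained`,
#'   `converged`.
#' @export
robust_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5) stop("need at least 5 finite (x, y) pairs")
  if (sd(x) == 0) stop("predictor has zero variance")
  fit <- tryCatch(
    suppressWarnings(MASS::rlm(y ~ x, psi = MASS::psi.bisquare,
                               maxit = 50)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    warning("robust fit did not converge; falling back to least squares")
    fit <- stats::lm(y ~ x)
    co <- stats::coef(fit)
    return(list(slope = unname(co[2]), intercept = unname(co[1]),
                variance_explained = stats::cor(stats::fitted(fit), y)^2,
                converged = FALSE))
  }
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]),
       variance_explained = stats::cor(stats::fitted(fit), y)^2,
       converged = TRUE)
}

#' Link PSD slope to short- and long-scale entropy
#'
#' Per group, robustly regresses each subject's mean entropy over a short
#' and a long scale band on the subject's mean-over-channels PSD slope,
#' quantifying how much of the entropy variation the 1/f slope explains.
#'
#' @param slope_maps list of `slope_map` objects.
#' @param mse_maps list of `mse_map` objects (matched by `subject_id`;
#'   unmatched subjects are dropped with a warning).
#' @param short_scales,long_scales scale bands (defaults 1:5 and 16:20).
#' @param by_group fit per group (default) or pooled.
#' @return data.frame, one row per group x band: `group`, `band`, `n`,
#'   `slope`, `intercept`, `variance_explained`.
#' @export
slope_mse_linkage <- function(slope_maps, mse_maps, short_scales = 1:5,
                              long_scales = 16:20, by_group = TRUE) {
  sid_s <- vapply(slope_maps, `[[`, character(1), "subject_id")
  sid_m <- vapply(mse_maps, `[[`, character(1), "subject_id")
  common <- intersect(sid_s, sid_m)
  if (length(common) < length(sid_s) || length(common) < length(sid_m))
    warning("subjects missing from one input were dropped")
  slope_maps <- slope_maps[match(common, sid_s)]
  mse_maps <- mse_maps[match(common, sid_m)]
  x <- vapply(slope_maps, function(s) mean(s$slope), numeric(1))
  grp <- vapply(mse_maps, function(m) as.character(m$group), character(1))
  band_mean <- function(m, sc) {
    cols <- match(intersect(sc, m$scales), m$scales)
    mean(m$values[, cols, drop = FALSE], na.rm = TRUE)
  }
  bands <- list(short = short_scales, long = long_scales)
  groups <- if (by_group) unique(grp) else "all"
  rows <- lapply(groups, function(g) {
    sel <- if (by_group) grp == g else rep(TRUE, length(grp))
    do.call(rbind, lapply(names(bands), function(bn) {
      y <- vapply(mse_maps[sel], band_mean, numeric(1), bands[[bn]])
      f <- robust_fit(x[sel], y)
      data.frame(group = g, band = bn, n = sum(sel), slope = f$slope,
                 intercept = f$intercept,
                 variance_explained = f$variance_explained)
    }))
  })
  do.call(rbind, rows)
}
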
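maps_to_array <- function(maps) {
  if (is.array(maps) && length(dim(maps)) == 3) return(maps)
  stopifnot(is.list(maps), length(maps) >= 1)
  v1 <- maps[[1]]$values
  arr <- array(NA_real_, c(length(maps), nrow(v1), ncol(v1)))
  for (i in seq_along(maps)) {
    vi <- maps[[i]]$values
    if (!all(dim(vi) == dim(v1))) stop("grid mismatch between subject maps")
    arr[i, , ] <- vi
  }
  dimnames(arr) <- c(list(NULL), dimnames(v1))
  arr
}

# Pooled-variance (or Welch) two-sample t per cell on flattened
# subject x cell matrices; complete-case per cell.
tmap_matrix <- function(xa, xb, welch = FALSE) {
  na <- colSums(!is.na(xa)); nb <- colSums(!is.na(xb))
  ma <- colMeans(xa, na.rm = TRUE); mb <- colMeans(xb, na.rm = TRUE)
  va <- colVars(xa, ma); vb <- colVars(xb, mb)
  if (welch) {
    se2 <- va / na + vb / nb
    t <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    t <- (mb - ma) / sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  t[na < 2 | nb < 2] <- NA_real_
  list(t = t, df = df)
}

colVars <- function(x, means) {
  n <- colSums(!is.na(x))
  colSums(sweep(x, 2, means)^2, na.rm = TRUE) / (n - 1)
}

#' Mass-univariate two-sample t map
#'
#' Per-cell independent-samples t statistic over a channel x bin grid
#' (bin = entropy scale or frequency), computed as group B minus group A
#' so that a larger second (conventionally older) group gives positive t.
#' Cells with undefined entries are handled by per-cell complete cases; a
#' cell with fewer than 2 subjects in either group is flagged missing.
#'
#' @param mapsA,mapsB lists of subject maps (`mse_map`/`psd_map`) or
#'   subject x channel x bin arrays, on identical grids.
#' @param welch use the Welch (unequal-variance) statistic instead of the
#'   pooled-variance default.
#' @return A `stat_map`: list with `t` (channel x bin matrix), `df`,
#'   `nA`, `nB`, `contrast`.
#' @export
two_sample_tmap <- function(mapsA, mapsB, welch = FALSE) {
  a <- maps_to_array(mapsA); b <- maps_to_array(mapsB)
  if (!all(dim(a)[2:3] == dim(b)[2:3]))
    stop("grid mismatch between groups")
  if (dim(a)[1] < 2 || dim(b)[1] < 2)
    stop("need at least 2 subjects per group")
  dm <- dim(a)[2:3]
  xa <- a; dim(xa) <- c(dim(a)[1], prod(dm))
  xb <- b; dim(xb) <- c(dim(b)[1], prod(dm))
  tm <- tmap_matrix(xa, xb, welch)
  t <- matrix(tm$t, dm[1], dm[2], dimnames = dimnames(a)[2:3])
  structure(list(t = t, df = tm$df, nA = dim(a)[1], nB = dim(b)[1],
                 contrast = c(groupA = groupname(mapsA),
                              groupB = groupname(mapsB)),
                 welch = welch),
            class = "stat_map")
}

groupname <- function(maps) {
  if (is.list(maps) && !is.null(maps[[1]]$group)) as.character(maps[[1]]$group)
  else NA_character_
}

#' Threshold-free cluster enhancement
#'
#' For each sign separately, `TFCE(cell) = sum_h e(h)^E * h^H * dh` over
#' thresholds from `dh` to the map maximum, where `e(h)` is the size of
#' the supra-threshold connected component containing the cell.
#' Connectivity combines channel adjacency (same bin) with +/- 1 bin
#' adjacency (same channel). The signed parts are recombined, so the
#' enhanced map has the sign pattern of the input. Missing (NA) cells are
#' excluded from components and stay NA.
#'
#' @param stat a `stat_map` or a channel x bin numeric matrix.
#' @param adjacency logical channel adjacency matrix (e.g.
#'   `montage$adjacency`).
#' @param E extent exponent (default 0.66).
#' @param H height exponent (default 2).
#' @param dh threshold step; `NULL` (default) uses the adaptive step
#'   max/100 per sign.
#' @return Channel x bin matrix of signed enhanced scores.
#' @export
tfce_enhance <- function(stat, adjacency, E = 0.66, H = 2, dh = NULL) {
  t <- if (inherits(stat, "stat_map")) stat$t else as.matrix(stat)
  if (!length(t)) stop("empty statistic map")
  if (nrow(adjacency) != nrow(t))
    stop("adjacency does not cover all channels")
  if (!is.null(dh) && dh <= 0) stop("dh must be positive")
  nbrs <- lapply(seq_len(nrow(adjacency)),
                 function(i) which(adjacency[i, ]) - 1L)
  out <- tfce_enhance_cpp(t, nbrs, E, H, if (is.null(dh)) -1 else dh)
  dimnames(out) <- dimnames(t)
  out
}

#' TFCE max-statistic permutation test
#'
#' Two-tailed familywise-error-controlled group contrast: the observed
#' t map is TFCE-enhanced; for each of `n_perm` random between-subject
#' label permutations the t map and enhancement are recomputed and the
#' maximum absolute enhanced score over all cells recorded. Per-cell
#' corrected p = `(1 + #\{null_max >= |observed|\}) / (1 + n_perm)`.
#'
#' @param mapsA,mapsB subject maps as in [two_sample_tmap()]; B minus A
#'   sign convention.
#' @param adjacency logical channel adjacency matrix.
#' @param E,H,dh TFCE parameters (see [tfce_enhance()]).
#' @param n_perm number of permutations (default 2000).
#' @param alpha nominal familywise level recorded in the result.
#' @param seed integer seed for the permutation stream.
#' @param welch use Welch t.
#' @return A `tfce_result`: list with `observed` (`stat_map`), `enhanced`,
#'   `null_max` (length `n_perm`), `p` (channel x bin matrix), `params`.
#' @export
permutation_test <- function(mapsA, mapsB, adjacency, E = 0.66, H = 2,
                             dh = NULL, n_perm = 2000, alpha = 0.05,
                             seed = 1, welch = FALSE) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  a <- maps_to_array(mapsA); b <- maps_to_array(mapsB)
  obs <- two_sample_tmap(a, b, welch)
  enh <- tfce_enhance(obs$t, adjacency, E, H, dh)
  nA <- dim(a)[1]; nB <- dim(b)[1]; nT <- nA + nB
  if (n_perm > choose(nT, nB))
    warning("n_perm exceeds the number of distinct label assignments; ",
            "permutations are sampled with replacement")
  dm <- dim(a)[2:3]
  x <- array(NA_real_, c(nT, dm))
  x[seq_len(nA), , ] <- a
  x[nA + seq_len(nB), , ] <- b
  dim(x) <- c(nT, prod(dm))
  nbrs <- lapply(seq_len(nrow(adjacency)),
                 function(i) which(adjacency[i, ]) - 1L)
  dh_c <- if (is.null(dh)) -1 else dh
  set.seed(as.integer(seed))
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    idx <- sample.int(nT, nB)
    tm <- tmap_matrix(x[-idx, , drop = FALSE], x[idx, , drop = FALSE],
                      welch)
    tp <- matrix(tm$t, dm[1], dm[2])
    ep <- tfce_enhance_cpp(tp, nbrs, E, H, dh_c)
    null_max[p] <- max(abs(ep), 0, na.rm = TRUE)
  }
  pmat <- matrix(NA_real_, dm[1], dm[2], dimnames = dimnames(obs$t))
  ok <- !is.na(enh)
  pmat[ok] <- (1 + vapply(abs(enh[ok]),
                          function(v) sum(null_max >= v),
                          numeric(1))) / (1 + n_perm)
  structure(list(observed = obs, enhanced = enh, null_max = null_max,
                 p = pmat,
                 params = list(E = E, H = H, dh = dh, n_perm = n_perm,
                               alpha = alpha, seed = seed, welch = welch)),
            class = "tfce_result")
}

#' @export
print.tfce_result <- function(x, ...) {
  cat(sprintf(
    "<tfce_result> %d x %d cells | %d perms | %d cell(s) p < %.3g\n",
    nrow(x$p), ncol(x$p), x$params$n_perm,
    sum(x$p < x$params$alpha, na.rm = TRUE), x$params$alpha))
  invisible(x)
}

#' Proportion of significant cells per region
#'
#' Summarizes a TFCE contrast as, per scalp region and overall, the
#' fraction of cells that are familywise-significant with the requested
#' sign (positive for entropy increases, negative for spectral-power
#' decreases).
#'
#' @param result a `tfce_result`.
#' @param alpha significance level (default 0.05).
#' @param montage the `eeg_montage` whose regions index the channels.
#' @param sign `"positive"` or `"negative"`.
#' @return data.frame with columns `region`, `n_cells`, `n_significant`,
#'   `proportion`.
#' @export
proportion_significant <- function(result, alpha = 0.05, montage,
                                   sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  sig <- result$p < alpha &
    (if (sign == "positive") result$observed$t > 0 else result$observed$t < 0)
  regions <- levels(droplevels(montage$region))
  rows <- lapply(c(regions, "overall"), function(rg) {
    chs <- if (rg == "overall") seq_along(montage$labels)
           else which(montage$region == rg)
    cells <- sig[chs, , drop = FALSE]
    data.frame(region = rg, n_cells = length(cells),
               n_significant = sum(cells, na.rm = TRUE),
               proportion = mean(cells, na.rm = TRUE))
  })
  do.call(rbind, rows)
}
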
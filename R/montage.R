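#' Construct a montage
#'
#' A montage describes the spatial layout of the electrode array: channel
#' labels, 2-D head-projection coordinates (unitless, nose up so +y is
#' anterior), a scalp region and hemisphere assignment per channel, and a
#' symmetric channel-neighbour (adjacency) relation used by cluster
#' statistics.
#'
#' @param labels character vector of unique channel names.
#' @param positions numeric n x 2 matrix of projected coordinates.
#' @param region character/factor, one of `"frontal"`, `"central"`,
#'   `"parieto_occipital"`, `"other"` per channel.
#' @param hemisphere character/factor, one of `"left"`, `"right"`,
#'   `"midline"` per channel.
#' @param adjacency optional logical n x n symmetric, irreflexive matrix;
#'   if `NULL` it is built with [build_adjacency()] using an automatic
#'   distance threshold.
#' @return An object of class `eeg_montage`.
#' @export
montage <- function(labels, positions, region, hemisphere, adjacency = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("montage labels must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(labels) || ncol(positions) != 2L)
    stop("positions must be an n x 2 matrix matching labels")
  region <- match_levels(region, c("frontal", "central", "parieto_occipital",
                                   "other"), "region")
  hemisphere <- match_levels(hemisphere, c("left", "right", "midline"),
                             "hemisphere")
  if (length(region) != length(labels) || length(hemisphere) != length(labels))
    stop("region and hemisphere must have one entry per channel")
  if (is.null(adjacency)) {
    adjacency <- build_adjacency(positions, max_dist = NULL)
  } else {
    adjacency <- as.matrix(adjacency)
    if (!isSymmetric(unname(adjacency * 1)))
      stop("adjacency must be symmetric")
    if (any(diag(adjacency)))
      stop("adjacency must be irreflexive (no self-neighbours)")
  }
  dimnames(adjacency) <- list(labels, labels)
  rownames(positions) <- labels
  structure(list(labels = labels, positions = positions,
                 region = region, hemisphere = hemisphere,
                 adjacency = adjacency),
            class = "eeg_montage")
}

match_levels <- function(x, levels, what) {
  x <- as.character(x)
  bad <- setdiff(unique(x), levels)
  if (length(bad))
    stop(sprintf("invalid %s value(s): %s", what, paste(bad, collapse = ", ")))
  factor(x, levels = levels)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d channels | regions: %s | median degree %d\n",
              length(x$labels),
              paste(levels(droplevels(x$region)), collapse = "/"),
              as.integer(median(rowSums(x$adjacency)))))
  invisible(x)
}

#' Build a channel adjacency relation from 2-D positions
#'
#' Channels i and j are neighbours iff their Euclidean distance is at most
#' `max_dist`. The relation is symmetric and irreflexive. With
#' `max_dist = NULL` the threshold is chosen automatically as the smallest
#' pairwise distance for which the median channel has at least 4 neighbours,
#' giving a connected but sparse graph suitable for cluster enhancement.
#'
#' @param positions numeric n x 2 coordinate matrix (n >= 2).
#' @param max_dist positive distance threshold, or `NULL` for automatic.
#' @return Logical n x n adjacency matrix.
#' @export
build_adjacency <- function(positions, max_dist = NULL) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) stop("need at least 2 channels to build adjacency")
  d <- as.matrix(dist(positions))
  offdiag <- d[upper.tri(d)]
  if (any(offdiag == 0))
    warning("duplicate channel positions detected")
  if (is.null(max_dist)) {
    # smallest threshold giving median degree >= 4 (capped at full graph)
    cand <- sort(unique(offdiag))
    deg_at <- function(md) median(rowSums(d <= md) - 1L)
    idx <- which(vapply(cand, deg_at, numeric(1)) >= min(4, n - 1))
    max_dist <- cand[idx[1L]]
  }
  if (max_dist <= 0) stop("max_dist must be positive")
  adj <- d <= max_dist
  diag(adj) <- FALSE
  if (all(!adj))
    warning("max_dist yields a fully disconnected adjacency graph")
  adj
}

#' Default dense-layout montage
#'
#' Deterministic sunflower-spiral layout of `n_channels` electrodes on the
#' unit disc (nose up, +y anterior). Channels are partitioned into
#' frontal/central/parieto-occipital thirds by anterior-posterior rank and
#' into left/right/midline by lateral position (|x| < 0.08 is midline). The
#' partition is a user-editable convention, not a reconstruction of any
#' particular cap's cluster memberships.
#'
#' @param n_channels number of electrodes (default 96, a dense array).
#' @return An `eeg_montage`.
#' @export
default_montage <- function(n_channels = 96) {
  stopifnot(n_channels >= 2)
  i <- seq_len(n_channels)
  golden <- pi * (3 - sqrt(5))
  r <- sqrt((i - 0.5) / n_channels)
  th <- i * golden
  pos <- cbind(x = r * cos(th), y = r * sin(th))
  yr <- rank(pos[, "y"], ties.method = "first")
  region <- rep("central", n_channels)
  region[yr > 2 * n_channels / 3] <- "frontal"
  region[yr <= n_channels / 3] <- "parieto_occipital"
  hemi <- ifelse(abs(pos[, "x"]) < 0.08, "midline",
                 ifelse(pos[, "x"] < 0, "left", "right"))
  labels <- sprintf("E%02d", i)
  montage(labels, pos, region, hemi)
}

#' Read a montage table
#'
#' Expects a delimited UTF-8 table with columns `label`, `x`, `y`,
#' `region`, `hemisphere`.
#'
#' @param path file path.
#' @param max_dist adjacency threshold passed to [build_adjacency()]
#'   (`NULL` = automatic).
#' @return An `eeg_montage`.
#' @export
read_montage <- function(path, max_dist = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "region", "hemisphere")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("montage file missing column(s): ", paste(miss, collapse = ", "))
  montage(tab$label, cbind(tab$x, tab$y), tab$region, tab$hemisphere,
          adjacency = if (is.null(max_dist)) NULL else
            build_adjacency(cbind(tab$x, tab$y), max_dist))
}

#' Write a montage table
#'
#' @param m an `eeg_montage`.
#' @param path output file path (tab-delimited).
#' @export
write_montage <- function(m, path) {
  tab <- data.frame(label = m$labels,
                    x = m$positions[, 1], y = m$positions[, 2],
                    region = as.character(m$region),
                    hemisphere = as.character(m$hemisphere))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
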
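# Shared in-code fixtures.

# Small montage with known region/hemisphere structure: 12 channels,
# 2 per region x hemisphere cell, laid out on a grid.
test_montage <- function() {
  grid <- expand.grid(x = c(-0.6, -0.3, 0.3, 0.6),
                      y = c(0.6, 0, -0.6))
  region <- rep(c("frontal", "central", "parieto_occipital"), each = 4)
  hemi <- rep(c("left", "left", "right", "right"), times = 3)
  montage(sprintf("T%02d", 1:12), as.matrix(grid), region, hemi,
          adjacency = build_adjacency(as.matrix(grid), max_dist = 0.65))
}

# Logistic-map series: deterministic, strongly nonlinear.
logistic_series <- function(n, x0 = 0.41, burn = 64) {
  x <- numeric(n + burn)
  x[1] <- x0
  for (i in 2:(n + burn)) x[i] <- 4 * x[i - 1] * (1 - x[i - 1])
  x[(burn + 1):(burn + n)]
}

# Subject maps on an arbitrary grid with a given cell-mean matrix.
sim_maps <- function(n_subj, mean_mat, sd = 1, group = "g", seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_subj), function(i) {
    v <- mean_mat + matrix(rnorm(length(mean_mat), 0, sd),
                           nrow(mean_mat))
    dimnames(v) <- list(sprintf("E%02d", seq_len(nrow(mean_mat))),
                        paste0("scale", seq_len(ncol(mean_mat))))
    structure(list(subject_id = sprintf("%s_%02d", group, i),
                   group = group, values = v,
                   scales = seq_len(ncol(mean_mat))),
              class = "mse_map")
  })
}
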
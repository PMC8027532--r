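# Independent brute-force oracles, deliberately written against the plain
# definitions (no shared code with the package implementations).

# Sample entropy by explicit template-pair enumeration: Chebyshev distance,
# strict < r, both template lengths drawn from the same N - m starting
# positions, self-matches excluded.
brute_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) < r) {
        A <- A + 1L
        if (abs(x[i + m] - x[j + m]) < r) B <- B + 1L
      }
    }
  }
  if (A == 0L || B == 0L) return(NA_real_)
  -log(B / A)
}

# TFCE by per-threshold connected-component labelling with igraph.
# Connectivity: channel-adjacent at same bin, or same channel at bin +/- 1.
brute_tfce <- function(tmap, adjacency, E, H, dh = NULL) {
  nch <- nrow(tmap); nb <- ncol(tmap)
  id <- function(ch, b) (b - 1L) * nch + ch
  edges <- NULL
  for (b in seq_len(nb)) {
    for (ch in seq_len(nch)) {
      if (b < nb) edges <- rbind(edges, c(id(ch, b), id(ch, b + 1L)))
      for (ch2 in which(adjacency[ch, ]))
        if (ch2 > ch) edges <- rbind(edges, c(id(ch, b), id(ch2, b)))
    }
  }
  g_all <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g_all <- igraph::add_vertices(
    g_all, max(0, nch * nb - igraph::vcount(g_all)))
  out <- matrix(0, nch, nb)
  for (sgn in c(1, -1)) {
    s <- pmax(sgn * tmap, 0)
    hmax <- max(s)
    if (hmax <= 0) next
    step <- if (is.null(dh)) hmax / 100 else dh
    for (k in seq_len(floor(hmax / step + 1e-9))) {
      h <- k * step
      supra <- which(as.vector(s) >= h)
      if (!length(supra)) next
      sub <- igraph::induced_subgraph(g_all, supra)
      comp <- igraph::components(sub)
      for (ci in seq_len(comp$no)) {
        cells <- supra[comp$membership == ci]
        out[cells] <- out[cells] +
          sgn * comp$csize[ci]^E * h^H * step
      }
    }
  }
  out
}

# Pairwise-distance adjacency by direct double loop.
brute_adjacency <- function(pos, max_dist) {
  n <- nrow(pos)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && sqrt(sum((pos[i, ] - pos[j, ])^2)) <= max_dist)
      adj[i, j] <- TRUE
  }
  adj
}
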
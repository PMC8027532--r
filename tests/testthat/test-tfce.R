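chain_adj <- function(n) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj
}

test_that("two-sample t map matches the pooled formula and is antisymmetric", {
  a <- sim_maps(6, matrix(0, 2, 2), sd = 1, group = "A", seed = 1)
  b <- sim_maps(8, matrix(1, 2, 2), sd = 1, group = "B", seed = 2)
  sm <- two_sample_tmap(a, b)
  # hand-computed pooled t at cell (1,1)
  xa <- vapply(a, function(m) m$values[1, 1], numeric(1))
  xb <- vapply(b, function(m) m$values[1, 1], numeric(1))
  sp2 <- ((5 * var(xa) + 7 * var(xb)) / 12)
  t_hand <- (mean(xb) - mean(xa)) / sqrt(sp2 * (1 / 6 + 1 / 8))
  expect_equal(sm$t[1, 1], t_hand, tolerance = 1e-12)
  # identical group means: t ~ 0 in expectation; antisymmetry is exact
  rev <- two_sample_tmap(b, a)
  expect_equal(rev$t, -sm$t, tolerance = 1e-12)
  expect_error(two_sample_tmap(a, sim_maps(3, matrix(0, 3, 2))),
               "grid mismatch")
  expect_error(two_sample_tmap(a[1], b), "at least 2")
})

test_that("missing cells use per-cell complete cases", {
  a <- sim_maps(5, matrix(0, 2, 2), group = "A", seed = 3)
  b <- sim_maps(5, matrix(0.5, 2, 2), group = "B", seed = 4)
  a[[1]]$values[1, 1] <- NA
  sm <- two_sample_tmap(a, b)
  xa <- vapply(a[-1], function(m) m$values[1, 1], numeric(1))
  xb <- vapply(b, function(m) m$values[1, 1], numeric(1))
  sp2 <- ((3 * var(xa) + 4 * var(xb)) / 7)
  expect_equal(sm$t[1, 1],
               (mean(xb) - mean(xa)) / sqrt(sp2 * (1 / 4 + 1 / 5)),
               tolerance = 1e-12)
  # a cell with < 2 subjects in one group is flagged missing
  for (i in 1:4) a[[i]]$values[2, 2] <- NA
  expect_true(is.na(two_sample_tmap(a, b)$t[2, 2]))
})

test_that("TFCE enhancement has closed-form and locality properties", {
  adj <- chain_adj(4)
  zero <- matrix(0, 4, 3)
  expect_equal(tfce_enhance(zero, adj), zero)
  # single isolated cell of height t0: enhancement ~ t0^(H+1)/(H+1)
  t0 <- 2.5
  m1 <- matrix(0, 4, 3); m1[1, 1] <- t0
  e1 <- tfce_enhance(m1, matrix(FALSE, 4, 4), E = 0.66, H = 2,
                     dh = t0 / 400)
  expect_equal(e1[1, 1], t0^3 / 3, tolerance = 0.01)
  # two disjoint clusters do not influence each other
  m2 <- m1; m2[4, 3] <- 1.8
  e2 <- tfce_enhance(m2, matrix(FALSE, 4, 4), dh = t0 / 400)
  e1b <- tfce_enhance(m1, matrix(FALSE, 4, 4), dh = t0 / 400)
  expect_equal(e2[1, 1], e1b[1, 1], tolerance = 1e-12)
  # sign pattern follows the statistic; negative part mirrors positive
  m3 <- m1; m3[1, 1] <- -t0
  e3 <- tfce_enhance(m3, matrix(FALSE, 4, 4), dh = t0 / 400)
  expect_equal(e3[1, 1], -e1[1, 1], tolerance = 1e-12)
  expect_error(tfce_enhance(matrix(0, 0, 0), adj), "empty")
  expect_error(tfce_enhance(m1, adj, dh = -1), "positive")
})

test_that("enhancement agrees with the igraph component oracle", {
  set.seed(121)
  for (rep in 1:6) {
    adj <- build_adjacency(matrix(runif(16), 8, 2), max_dist = 0.4)
    tm <- matrix(rnorm(8 * 6), 8, 6)
    dh <- max(abs(tm)) / 80
    got <- tfce_enhance(tm, adj, E = 0.66, H = 2, dh = dh)
    want <- brute_tfce(tm, adj, E = 0.66, H = 2, dh = dh)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("enhancement is monotone in map scale and stable in dh", {
  set.seed(131)
  adj <- chain_adj(6)
  tm <- matrix(rnorm(6 * 5), 6, 5)
  e1 <- tfce_enhance(tm, adj)
  e2 <- tfce_enhance(2 * tm, adj)
  nz <- abs(e1) > 1e-12
  expect_true(all(abs(e2[nz]) > abs(e1[nz])))
  # halving the step changes scores by well under 1 % of the map scale
  hmax <- max(abs(tm))
  a <- tfce_enhance(tm, adj, dh = hmax / 100)
  b <- tfce_enhance(tm, adj, dh = hmax / 200)
  expect_lt(max(abs(a - b)) / max(abs(a)), 0.02)
})

test_that("permutation p-values hit the exact floor for dominant effects", {
  a <- sim_maps(6, matrix(0, 3, 3), sd = 0.2, group = "A", seed = 5)
  b <- sim_maps(6, matrix(4, 3, 3), sd = 0.2, group = "B", seed = 6)
  res <- permutation_test(a, b, chain_adj(3), n_perm = 200, seed = 8)
  expect_equal(min(res$p), 1 / 201)
  expect_true(all(res$p >= 1 / 201 & res$p <= 1))
  # enhanced map carries the sign of t
  expect_true(all(sign(res$enhanced[res$observed$t != 0]) ==
                    sign(res$observed$t[res$observed$t != 0])))
  expect_warning(
    permutation_test(a[1:2], b[1:2], chain_adj(3), n_perm = 100,
                     seed = 8),
    "with replacement")
})

test_that("proportion summaries count signed significant cells by region", {
  mont <- test_montage()
  p <- matrix(1, 12, 5)
  t <- matrix(1, 12, 5)
  p[1, 1:3] <- 0.01          # frontal channel, positive
  p[12, 1] <- 0.01; t[12, 1] <- -1  # parieto-occipital, negative
  res <- structure(list(observed = list(t = t), p = p,
                        params = list(alpha = 0.05, n_perm = 100)),
                   class = "tfce_result")
  pos <- proportion_significant(res, 0.05, mont, sign = "positive")
  expect_equal(pos$proportion[pos$region == "frontal"], 3 / 20)
  expect_equal(pos$proportion[pos$region == "parieto_occipital"], 0)
  expect_equal(pos$proportion[pos$region == "overall"], 3 / 60)
  neg <- proportion_significant(res, 0.05, mont, sign = "negative")
  expect_equal(neg$proportion[neg$region == "parieto_occipital"], 1 / 20)
  # alpha = 0 flags nothing
  zero <- proportion_significant(res, 0, mont)
  expect_true(all(zero$proportion == 0))
})
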
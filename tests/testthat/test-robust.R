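test_that("trimmed mean matches the sort-and-slice definition", {
  expect_equal(trimmed_mean(1:10, 0.2), mean(3:8))
  expect_equal(trimmed_mean(c(4, 1, 3, 2), 0), 2.5)
  set.seed(141)
  for (rep in 1:20) {
    x <- rnorm(sample(5:40, 1))
    tr <- runif(1, 0, 0.4)
    expect_equal(trimmed_mean(x, tr), mean(x, trim = tr),
                 tolerance = 1e-12)
  }
  # an outlier moves the trimmed mean less than the mean
  set.seed(142)
  x <- rnorm(20)
  xo <- c(x, 50)
  expect_lt(abs(trimmed_mean(xo, 0.2) - trimmed_mean(x, 0.2)),
            abs(mean(xo) - mean(x)))
  expect_error(trimmed_mean(c(1, 2), 0.5), "trimmed")
})

test_that("region-hemisphere cells average the right channels", {
  mont <- test_montage()
  vals <- matrix(seq_len(12 * 4), 12, 4)  # channel x scale
  maps <- list(structure(list(subject_id = "s1", group = "g",
                              values = vals, scales = 1:4),
                         class = "mse_map"))
  cells <- region_hemisphere_cells(maps, mont)
  chmeans <- rowMeans(vals)
  expect_equal(cells$frontal_left,
               mean(chmeans[mont$region == "frontal" &
                              mont$hemisphere == "left"]))
  expect_equal(cells$parieto_occipital_right,
               mean(chmeans[mont$region == "parieto_occipital" &
                              mont$hemisphere == "right"]))
})

test_that("bootstrap contrasts are deterministic and detect a shift", {
  set.seed(151)
  n <- 25
  cells <- data.frame(subject_id = seq_len(n), group = "g",
                      frontal_left = rnorm(n), frontal_right = rnorm(n),
                      central_left = rnorm(n), central_right = rnorm(n),
                      parieto_occipital_left = rnorm(n),
                      parieto_occipital_right = rnorm(n))
  r1 <- ww_trimmed_bootstrap(cells, n_boot = 400, seed = 7)
  r2 <- ww_trimmed_bootstrap(cells, n_boot = 400, seed = 7)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 7)
  expect_true(all(r1$lower <= r1$upper))
  expect_true(all(r1$p > 0 & r1$p <= 1))

  # large frontal shift: frontal-vs-posterior contrast excludes zero
  shifted <- cells
  shifted$frontal_left <- shifted$frontal_left + 3
  shifted$frontal_right <- shifted$frontal_right + 3
  rs <- ww_trimmed_bootstrap(shifted, n_boot = 400, seed = 7)
  row <- rs[rs$contrast == "region_frontal_vs_parieto_occipital", ]
  expect_gt(row$lower, 0)
  expect_lt(row$p, 0.05)
  expect_error(ww_trimmed_bootstrap(cells[1:5, ]), "at least 10")
  expect_error(ww_trimmed_bootstrap(cells[, -3]), "missing cell")
})

test_that("robust fit recovers exact lines and resists gross outliers", {
  x <- seq(-2, 2, length.out = 40)
  f <- robust_fit(x, 2 * x)
  expect_equal(f$slope, 2, tolerance = 1e-9)
  expect_equal(f$variance_explained, 1, tolerance = 1e-9)
  set.seed(161)
  y <- 2 * x + rnorm(40, 0, 0.05)
  y[sample(40, 4)] <- y[sample(40, 4)] + 30  # 10% gross outliers
  expect_lt(abs(robust_fit(x, y)$slope - 2), 0.1)
  # independent response: negligible variance explained on average
  ve <- vapply(1:25, function(i) {
    set.seed(700 + i)
    robust_fit(rnorm(50), rnorm(50))$variance_explained
  }, numeric(1))
  expect_lt(mean(ve), 0.05)
  expect_error(robust_fit(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(robust_fit(1:3, 1:3), "at least 5")
})

test_that("slope-entropy linkage is strong when beta drives entropy, null otherwise", {
  # entropy driven by between-subject beta variation: strong linkage;
  # all generator parameters fixed (entropy and slope vary only by
  # estimation noise): negligible linkage
  mk_cohort <- function(vary_beta, seed) {
    set.seed(seed)
    n <- 14
    betas <- if (vary_beta) runif(n, 0.6, 2.4) else rep(1.5, n)
    mixes <- if (vary_beta) rep(0, n) else rep(0.35, n)
    slope_maps <- list(); mse_maps <- list()
    for (i in seq_len(n)) {
      x <- (1 - mixes[i]) * colored_noise(betas[i], 5120, 256,
                                          seed = seed + i) +
        mixes[i] * rnorm(5120)
      x <- (x - mean(x)) / sd(x)
      ps <- welch_psd(x, 256, win_len = 512)
      sl <- loglog_slope(ps$freqs, ps$power)$slope
      mv <- matrix(mse_curve(x, mse_params(scales = 1:5)), 1)
      dimnames(mv) <- list("E01", paste0("scale", 1:5))
      sid <- sprintf("s%02d", i)
      slope_maps[[i]] <- structure(list(subject_id = sid, group = "g",
                                        slope = sl),
                                   class = "slope_map")
      mse_maps[[i]] <- structure(list(subject_id = sid, group = "g",
                                      values = mv, scales = 1:5),
                                 class = "mse_map")
    }
    slope_mse_linkage(slope_maps, mse_maps, short_scales = 1:3,
                      long_scales = 4:5)
  }
  strong <- mk_cohort(TRUE, 7000)
  weak <- mk_cohort(FALSE, 8000)
  expect_gt(strong$variance_explained[strong$band == "short"], 0.5)
  expect_lt(weak$variance_explained[weak$band == "short"], 0.3)
  # unmatched subjects are dropped with a warning
  sm <- sim_maps(6, matrix(1, 2, 5), group = "g", seed = 1)
  sl <- lapply(1:5, function(i)
    structure(list(subject_id = sprintf("g_%02d", i), group = "g",
                   slope = -1.5 + 0.1 * i), class = "slope_map"))
  expect_warning(slope_mse_linkage(sl, sm, 1:2, 4:5), "dropped")
})
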
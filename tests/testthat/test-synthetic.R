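test_that("colored noise is reproducible, standardized, and validated", {
  x <- colored_noise(1, 4096, 512, seed = 5)
  expect_identical(x, colored_noise(1, 4096, 512, seed = 5))
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  expect_error(colored_noise(1, 1), "n must be")
  # odd lengths keep the signal real
  y <- colored_noise(2, 4097, 512, seed = 5)
  expect_length(y, 4097)
  expect_true(all(is.finite(y)))
})

test_that("colored-noise spectral exponent is recovered by the PSD fit", {
  # light recovery check (the seed-ensemble version runs with the
  # acceptance suite)
  for (beta in c(0, 2)) {
    slopes <- vapply(1:5, function(s) {
      x <- colored_noise(beta, 2^15, 512, seed = 200 + s)
      ps <- welch_psd(x, 512)
      loglog_slope(ps$freqs, ps$power)$slope
    }, numeric(1))
    expect_lt(abs(mean(slopes) - (-beta)), 0.15)
  }
})

test_that("irregularity mix raises fine-scale entropy monotonically", {
  ent <- vapply(c(0, 0.3, 0.6), function(mix) {
    mean(vapply(1:8, function(i) {
      spec <- cohort_spec(list(cohort_group("g", 2,
                                            irregularity_mix = mix,
                                            alpha_amp = 0)),
                          n_channels = 2, fs = 64, duration_s = 20,
                          seed = 1)
      rec <- generate_subject(spec, "g", subject_seed = 400 + i)
      x <- rec$data[1, ]
      sample_entropy(x, 2, 0.5 * sd(x))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ent) > 0))
})

test_that("alpha component shows as a PSD peak at the alpha frequency", {
  spec <- cohort_spec(list(cohort_group("g", 2, irregularity_mix = 0,
                                        alpha_amp = 2,
                                        alpha_freq_hz = 10)),
                      n_channels = 2, fs = 128, duration_s = 24, seed = 3)
  rec <- generate_subject(spec, "g", subject_seed = 77)
  ps <- welch_psd(rec$data[1, ], 128, win_len = 256, fmin = 2, fmax = 30)
  peak <- ps$freqs[which.max(ps$power)]
  expect_equal(peak, 10, tolerance = 0.5)
})

test_that("cohorts are balanced, labelled, and byte-identical under a seed", {
  spec <- cohort_spec(list(cohort_group("a", 3), cohort_group("b", 3)),
                      n_channels = 4, fs = 64, duration_s = 20, seed = 9)
  coh <- generate_cohort(spec)
  expect_length(coh$recordings, 6)
  expect_equal(as.vector(table(coh$manifest$group)), c(3, 3))
  coh2 <- generate_cohort(spec)
  expect_identical(coh$recordings[[5]]$data, coh2$recordings[[5]]$data)
  expect_identical(coh$manifest, coh2$manifest)
})

test_that("cohort spec validation rejects malformed groups", {
  expect_error(cohort_spec(list(cohort_group("a", 1)), 4, 64, 20),
               "n_subjects")
  expect_error(cohort_spec(list(cohort_group("a", 3,
                                             irregularity_mix = 1.2)),
                           4, 64, 20), "irregularity_mix")
  expect_error(cohort_spec(list(cohort_group("a", 3)), 4, 64,
                           duration_s = 10), "duration_s")
  expect_error(generate_subject(cohort_spec(list(cohort_group("a", 3)),
                                            4, 64, 20), "zzz", 1),
               "unknown group")
})

test_that("group effects are restricted to the effect channels", {
  spec <- cohort_spec(list(cohort_group("ref", 2, irregularity_mix = 0,
                                        alpha_amp = 0),
                           cohort_group("eff", 2, irregularity_mix = 0.8,
                                        alpha_amp = 0)),
                      n_channels = 4, fs = 64, duration_s = 20,
                      effect_channels = 1:2, seed = 5)
  ent <- function(x) sample_entropy(x, 2, 0.5 * sd(x))
  d <- vapply(1:6, function(i) {
    rec <- generate_subject(spec, "eff", subject_seed = 600 + i)
    c(on = mean(ent(rec$data[1, ]), ent(rec$data[2, ])),
      off = mean(ent(rec$data[3, ]), ent(rec$data[4, ])))
  }, numeric(2))
  ref <- vapply(1:6, function(i) {
    rec <- generate_subject(spec, "ref", subject_seed = 900 + i)
    mean(ent(rec$data[1, ]), ent(rec$data[2, ]))
  }, numeric(1))
  # effect channels of the effect group are clearly more irregular than
  # both their own off-effect channels and the reference group
  expect_gt(mean(d["on", ]) - mean(d["off", ]), 0.2)
  expect_gt(mean(d["on", ]) - mean(ref), 0.2)
  expect_lt(abs(mean(d["off", ]) - mean(ref)), 0.2)
})
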
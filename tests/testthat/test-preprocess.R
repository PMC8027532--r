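mont2 <- function() montage(c("a", "b"), cbind(c(0, 1), c(0, 0)),
                            rep("frontal", 2), rep("left", 2))

test_that("low-pass preserves the passband and DC, kills the stopband", {
  m <- mont2()
  tg <- (0:(512 * 4 - 1)) / 512
  rec <- recording(rbind(sin(2 * pi * 5 * tg), sin(2 * pi * 60 * tg)),
                   512, m)
  filt <- lowpass(rec, 30)
  # 5 Hz amplitude preserved within 1 %
  expect_equal(sd(filt$data[1, ]), sd(rec$data[1, ]), tolerance = 0.01)
  # 60 Hz attenuated by at least 20 dB
  expect_lt(20 * log10(sd(filt$data[2, ]) / sd(rec$data[2, ])), -20)
  # constant signal passes unchanged
  const <- recording(matrix(3.5, 2, 2048), 512, m)
  expect_equal(lowpass(const, 30)$data, const$data, tolerance = 1e-6)
  expect_error(lowpass(rec, 300), "Nyquist")
})

test_that("segmentation partitions the recording into whole epochs", {
  m <- mont2()
  fs <- 64
  rec <- recording(matrix(seq_len(2 * 65 * fs), 2, byrow = TRUE), fs, m)
  es <- segment_epochs(rec, 20)
  expect_equal(dim(es$epochs), c(3, 2, 20 * fs))
  # concatenating epochs reproduces the first 60 s exactly
  expect_equal(as.vector(t(cbind(es$epochs[1, , ], es$epochs[2, , ],
                                 es$epochs[3, , ]))),
               as.vector(t(rec$data[, 1:(60 * fs)])))
  short <- recording(matrix(0, 2, 19 * fs), fs, m)
  expect_error(segment_epochs(short, 20), "shorter than one")
})

test_that("extreme-voltage rejection uses a strict boundary and is monotone", {
  m <- mont2()
  ep <- array(0, c(3, 2, 32))
  ep[1, 1, 5] <- 200
  ep[2, 2, 9] <- 150   # exactly at the boundary: retained
  es <- reject_extreme(epoch_set(ep, 64, m), 150)
  expect_identical(es$rejected, c(TRUE, FALSE, FALSE))
  expect_identical(es$reason[1], "extreme_voltage")
  # idempotent
  expect_identical(reject_extreme(es, 150)$rejected, es$rejected)
  # loosening the threshold never rejects more
  looser <- reject_extreme(epoch_set(ep, 64, m), 250)
  expect_true(all(looser$rejected <= es$rejected))
})

test_that("rejection is order-independent", {
  set.seed(21)
  ep <- array(rnorm(12 * 2 * 64, 0, 50), c(12, 2, 64))
  ep[3, 1, 10] <- 400
  m <- mont2()
  flags <- reject_extreme(epoch_set(ep, 64, m), 150)$rejected
  perm <- sample(12)
  flags_p <- reject_extreme(epoch_set(ep[perm, , , drop = FALSE], 64, m),
                            150)$rejected
  expect_identical(flags_p, flags[perm])
})

test_that("joint-probability rule flags the improbable epoch", {
  m <- mont2()
  # identical epochs: all z-scores zero, nothing rejected
  ep0 <- array(rep(rnorm(64), each = 10), c(10, 2, 32))
  es0 <- reject_jointprob(epoch_set(ep0, 64, m), 5)
  expect_false(any(es0$rejected))

  # planted extreme-tail epoch attains the maximum |z| among 10 epochs
  set.seed(31)
  ep <- array(rnorm(10 * 2 * 256), c(10, 2, 256))
  ep[4, 1, ] <- rnorm(256, 0, 6)
  es <- reject_jointprob(epoch_set(ep, 64, m), 5)
  z <- attr(es, "jp_z")
  expect_equal(which.max(apply(abs(z), 1, max)), 4)

  # an infinite threshold rejects nothing
  esi <- reject_jointprob(epoch_set(ep, 64, m), Inf)
  expect_false(any(esi$rejected))

  # constant channel is skipped with a warning, not an error
  epc <- ep; epc[, 2, ] <- 1
  expect_warning(reject_jointprob(epoch_set(epc, 64, m), 5), "constant")

  # too few epochs: rule skipped with warning
  expect_warning(reject_jointprob(epoch_set(ep[1:2, , , drop = FALSE],
                                            64, m), 5),
                 "fewer than 3")
})

test_that("preprocess chains filtering, segmentation, and rejection", {
  m <- mont2()
  set.seed(41)
  dat <- matrix(rnorm(2 * 64 * 70, 0, 20), 2)
  dat[1, 300] <- 500  # artifact in the first epoch
  rec <- recording(dat, 64, m)
  es <- preprocess(rec, lowpass_hz = 25, epoch_len_s = 20,
                   amp_thresh = 150)
  expect_s3_class(es, "epoch_set")
  expect_equal(dim(es$epochs)[1], 3)
  qc <- qc_table(es)
  expect_equal(nrow(qc), 3)
  expect_true(all(qc$retained | nzchar(qc$reason)))
})
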
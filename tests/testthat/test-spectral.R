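test_that("Welch PSD conserves power and resolves pure tones", {
  set.seed(30)
  fs <- 256
  x <- rnorm(fs * 60)
  sp <- welchPSD(x, fs)
  totalPower <- sum(sp$psd) * (sp$freq[2] - sp$freq[1])
  expect_equal(totalPower, var(x), tolerance = 0.05)

  tt <- (0:(fs * 20 - 1)) / fs
  sp10 <- welchPSD(sin(2 * pi * 10 * tt), fs)
  expect_equal(sp10$freq[which.max(sp10$psd)], 10, tolerance = 0.5)

  expect_error(welchPSD(x[1:100], fs), "shorter than one Welch segment")
})

test_that("dominant frequency finds the strongest rhythm in band", {
  fs <- 256
  tt <- (0:(fs * 30 - 1)) / fs
  set.seed(31)
  mk <- function(sig) newRecording(matrix(rep(sig, 8), 8, byrow = TRUE) +
    rnorm(8 * length(sig), sd = 1e-3), fs)

  rec10 <- mk(sin(2 * pi * 10 * tt))
  expect_equal(dominantFrequency(rec10), 10, tolerance = 0.5)
  # invariant to signal scaling
  rec10s <- newRecording(eegData(rec10) * 250, fs)
  expect_equal(dominantFrequency(rec10s), dominantFrequency(rec10))

  # 6 Hz at twice the amplitude of 12 Hz dominates
  rec612 <- mk(2 * sin(2 * pi * 6 * tt) + sin(2 * pi * 12 * tt))
  expect_equal(dominantFrequency(rec612), 6, tolerance = 0.5)

  # per-epoch estimates averaged for an EpochSet
  ep <- epochAndSelect(rec10, 2, 10)
  expect_equal(dominantFrequency(ep), 10, tolerance = 0.5)

  expect_error(dominantFrequency(rec10, channels = "Oz"), "not present")
  expect_error(dominantFrequency(rec10, band = c(4, 4.4)), "unresolvable")
})

test_that("band powers integrate the spectrum correctly", {
  fs <- 256
  tt <- (0:(fs * 30 - 1)) / fs
  set.seed(32)
  rec <- newRecording(
    matrix(rep(sin(2 * pi * 10 * tt), 4), 4, byrow = TRUE) +
      rnorm(4 * length(tt), sd = 1e-3), fs
  )
  rel <- bandPower(rec, relative = TRUE)
  expect_equal(sum(rel), 1, tolerance = 1e-12)
  expect_gt(rel["alpha"], 0.99) # a 10 Hz tone lives in the alpha band

  # 1/f-shaped noise: low-frequency bands dominate high ones
  n <- fs * 60
  # shape white noise in the frequency domain with a symmetric 1/sqrt(f)
  # gain (Hermitian symmetry preserved, so the inverse transform is real)
  f <- c(1, pmin(seq_len(n - 1), n - seq_len(n - 1)))
  x1f <- Re(fft(fft(rnorm(n)) / sqrt(f), inverse = TRUE)) / n
  rec1f <- newRecording(rbind(x1f, x1f), fs)
  bp <- bandPower(rec1f)
  expect_gt(bp["delta"], bp["beta"])

  expect_error(bandPower(rec, bands = list(hi = c(100, 200))), "Nyquist")
  expect_error(
    bandPower(rec, bands = list(a = c(1, 5), b = c(4, 8))),
    "non-overlapping"
  )
})

test_that("the occipital montage subset is available by name or positionally", {
  occ <- occipitalChannels()
  expect_true(all(c("O1", "O2", "Oz", "PO9", "PO10") %in% occ))
  expect_identical(occipitalChannels(3), c("Ch1", "Ch2", "Ch3"))
})
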
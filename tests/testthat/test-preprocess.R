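test_that("band-pass removes DC and matches the analytic Butterworth response", {
  fs <- 256
  tt <- (0:(fs * 10 - 1)) / fs

  dc <- bandpassFilter(newRecording(matrix(5, 2, fs * 4), fs), 2, 20, 2)
  expect_lt(max(abs(eegData(dc))), 1e-6 * 5)

  mid <- (fs * 2):(fs * 8) # avoid filtfilt edge transients
  measure <- function(freq) {
    rec <- newRecording(rbind(sin(2 * pi * freq * tt), -sin(2 * pi * freq * tt)), fs)
    y <- eegData(bandpassFilter(rec, 2, 20, 2))[1, mid]
    (max(y) - min(y)) / 2
  }
  amp10 <- measure(10)
  amp40 <- measure(40)
  # zero-phase = squared magnitude of the single-pass design
  expect_equal(amp10, butterZeroPhaseGain(10, 2, 20, 2, fs), tolerance = 0.01)
  expect_equal(amp10, 1, tolerance = 0.05) # 10 Hz sits in the passband
  expect_equal(amp40, butterZeroPhaseGain(40, 2, 20, 2, fs), tolerance = 0.05)
  expect_lt(amp40, amp10 / 5) # 40 Hz clearly attenuated

  expect_error(
    bandpassFilter(newRecording(matrix(0, 2, 100), 100), 2, 60, 2),
    "Nyquist|band edges"
  )
})

test_that("filtering is linear", {
  fs <- 128
  set.seed(1)
  x <- matrix(rnorm(2 * fs * 5), 2)
  y <- matrix(rnorm(2 * fs * 5), 2)
  fx <- eegData(bandpassFilter(newRecording(x, fs), 2, 20, 2))
  fy <- eegData(bandpassFilter(newRecording(y, fs), 2, 20, 2))
  fxy <- eegData(bandpassFilter(newRecording(3 * x - 2 * y, fs), 2, 20, 2))
  expect_equal(fxy, 3 * fx - 2 * fy, tolerance = 1e-8)
})

test_that("average reference zeroes channel means, idempotently", {
  set.seed(2)
  rec <- newRecording(matrix(rnorm(8 * 100), 8), 100)
  ar <- averageReference(rec)
  expect_lt(max(abs(colMeans(eegData(ar)))), 1e-12)
  expect_identical(referenceState(ar), "average")
  expect_equal(eegData(averageReference(ar)), eegData(ar))
  # common-mode invariance
  shifted <- newRecording(eegData(rec) + 42, 100)
  expect_equal(eegData(averageReference(shifted)), eegData(ar))
  expect_error(averageReference(newRecording(matrix(1, 1, 10), 10)), "2 channels")
})

test_that("epoch selection keeps the first clean epochs in order", {
  fs <- 100
  x <- matrix(sin(seq_len(fs * 150) / 10), 4, fs * 150, byrow = TRUE)
  rec <- newRecording(x, fs)
  ep <- epochAndSelect(rec, 2, 30)
  expect_equal(dim(epochsArray(ep)), c(30L, 4L, 200L))
  # first 30 epochs come from the first 60 s, contiguously
  expect_equal(epochsArray(ep)[1, , ], x[, 1:200])
  expect_equal(epochsArray(ep)[30, , ], x[, (29 * 200 + 1):(30 * 200)])
  # concatenating retained epochs reproduces the source samples exactly
  recon <- do.call(cbind, lapply(1:30, function(e) epochsArray(ep)[e, , ]))
  expect_identical(recon, x[, 1:6000])

  # planted spike in epoch 3 drops it and promotes the next clean epoch
  x2 <- x
  x2[2, 2 * 200 + 50] <- 10000
  ep2 <- epochAndSelect(newRecording(x2, fs), 2, 30, rejectThresholdUv = 500)
  expect_equal(epochsArray(ep2)[3, , ], x[, (3 * 200 + 1):(4 * 200)])

  expect_error(
    epochAndSelect(newRecording(x[, 1:(10 * fs)], fs), 2, 30),
    "excluded"
  )
})
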
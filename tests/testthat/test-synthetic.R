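test_that("generated topographies are average-referenced, unit-RMS and separated", {
  one <- makeTopographies(128, 1, seed = 3)
  expect_equal(ncol(one), 1L)
  expect_lt(abs(mean(one)), 1e-12)

  tpl <- makeTopographies(64, 5, seed = 7)
  expect_equal(dim(tpl), c(64L, 5L))
  expect_true(all(abs(colMeans(tpl)) < 1e-12))
  expect_equal(unname(colMeans(tpl^2)), rep(1, 5)) # unit RMS
  cc <- abs(crossprod(tpl) / 64)
  expect_true(all(cc[upper.tri(cc)] < 0.5)) # all C(5,2) pairs separated

  expect_identical(tpl, makeTopographies(64, 5, seed = 7)) # determinism
  expect_error(makeTopographies(4, 2), "nChannels")
  expect_error(
    makeTopographies(16, 10, seed = 1, maxAbsCorrelation = 0.01, maxRetries = 3),
    "0.01"
  ) # unattainable bound named in the failure
})

test_that("noise-free simulation reproduces the active template at every sample", {
  tpl <- makeTopographies(32, 3, seed = 1)
  sim <- simulateMicrostateEEG(tpl, 80, 256, 2, carrierHz = 10, snr = Inf, seed = 4)
  x <- eegData(sim$recording)
  lab <- sim$groundTruth$labelSequence
  g <- sqrt(colMeans(x^2))
  idx <- which(g > 0.1) # away from carrier zero crossings
  for (t in idx[seq(1, length(idx), by = 17)]) {
    expect_equal(abs(spatialCorrelation(x[, t], tpl[, lab[t]])), 1, tolerance = 1e-9)
  }
  # exact average reference at every sample
  expect_lt(max(abs(colMeans(x))), 1e-12)
  # determinism
  sim2 <- simulateMicrostateEEG(tpl, 80, 256, 2, carrierHz = 10, snr = Inf, seed = 4)
  expect_identical(eegData(sim$recording), eegData(sim2$recording))
})

test_that("realized dwell times match the planted geometric mean", {
  tpl <- makeTopographies(8, 4, seed = 2)
  meanRun <- sapply(1:20, function(s) {
    sim <- simulateMicrostateEEG(tpl, 80, 256, 60, snr = Inf, seed = s)
    mean(rle(sim$groundTruth$labelSequence)$lengths) / 256 * 1000
  })
  expect_gt(mean(meanRun), 72) # within 10% of 80 ms
  expect_lt(mean(meanRun), 88)
})

test_that("a 10 Hz carrier yields about 20 GFP peaks per second", {
  tpl <- makeTopographies(16, 3, seed = 5)
  sim <- simulateMicrostateEEG(tpl, 80, 256, 2, carrierHz = 10, snr = Inf, seed = 6)
  g <- computeGFP(eegData(sim$recording))
  expect_gte(length(g$peaks), 39)
  expect_lte(length(g$peaks), 41)
})

test_that("simulation rejects invalid parameters", {
  tpl <- makeTopographies(16, 3, seed = 5)
  expect_error(simulateMicrostateEEG(tpl, 80, fs = -1, durationS = 2), "fs")
  expect_error(simulateMicrostateEEG(tpl, 80, fs = 256, durationS = 0), "durationS")
  expect_error(simulateMicrostateEEG(tpl, 2, fs = 256, durationS = 2), "dwellMeanMs")
  expect_error(simulateMicrostateEEG(tpl, 80, fs = 256, durationS = 2, snr = -1), "snr")
})

test_that("cohorts share templates, respect dwell ordering, and are reproducible", {
  co <- simulateCohort(c(1, 1), c(65, 77), nChannels = 16, k = 3, durationS = 5, seed = 8)
  expect_length(co$subjects, 2L)

  co2 <- simulateCohort(c(1, 1), c(65, 77), nChannels = 16, k = 3, durationS = 5, seed = 8)
  expect_identical(
    eegData(co$subjects[[2]]$recording),
    eegData(co2$subjects[[2]]$recording)
  )

  co3 <- simulateCohort(c(5, 5), c(65, 77),
    nChannels = 8, k = 4, durationS = 30,
    snr = Inf, seed = 9
  )
  dwell <- vapply(co3$subjects, function(s) {
    mean(rle(s$groundTruth$labelSequence)$lengths) / 256 * 1000
  }, numeric(1))
  grp <- vapply(co3$subjects, `[[`, "", "group")
  expect_lt(mean(dwell[grp == "G1"]), mean(dwell[grp == "G2"]))

  expect_error(simulateCohort(integer(0), numeric(0), seed = 1), "empty")
})

test_that("network time courses honor the state covariances", {
  st <- switchingStates(5, 0.8)
  expect_error(
    simulateNetworkTimecourses(5, 0, 2, st, seed = 1),
    "nVolumes"
  )
  bad <- st
  bad[[2]] <- matrix(1, 5, 5) # rank-1: not positive definite
  expect_error(
    simulateNetworkTimecourses(5, 100, 2, bad, seed = 1),
    "state 2"
  )

  # single state: stationary, empirical correlation near the planted one
  one <- simulateNetworkTimecourses(5, 4000, 2, st[1], seed = 2)
  expect_true(all(one$stateSequence == 1L))
  expect_equal(cor(t(networkData(one$timecourses)))[1, 2], 0.8, tolerance = 0.05)

  # two states: full-series correlation near the dwell-weighted mixture
  two <- simulateNetworkTimecourses(5, 6000, 2, st, dwellVolumes = 25, seed = 3)
  w1 <- mean(two$stateSequence == 1L)
  expected <- w1 * 0.8 + (1 - w1) * (-0.8)
  observed <- cor(t(networkData(two$timecourses)))[1, 2]
  expect_equal(observed, expected, tolerance = 0.06)
})
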
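test_that("back-fitting labels GFP peaks by the planted template at infinite SNR", {
  tpl <- makeTopographies(32, 4, seed = 16)
  sim <- simulateMicrostateEEG(tpl, 80, 256, 10, carrierHz = 10, snr = Inf, seed = 16)
  ep <- epochAndSelect(sim$recording, 2, 5)
  seg <- backfit(tpl, ep, mode = "peaks_interpolated")
  gt <- sim$groundTruth$labelSequence
  spe <- 512L
  for (e in 1:5) {
    g <- computeGFP(epochsArray(ep)[e, , ])
    expect_identical(
      stateLabels(seg)[e, g$peaks],
      gt[(e - 1L) * spe + g$peaks]
    )
  }
})

test_that("interpolation splits an even inter-peak gap at the midpoint", {
  set.seed(17)
  a <- rnorm(16)
  a <- a - mean(a)
  b <- rnorm(16)
  b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a * a)
  a <- a / sqrt(mean(a^2))
  b <- b / sqrt(mean(b^2))
  wA <- c(seq(0.1, 1, length.out = 11), seq(0.9, 0.1, length.out = 4), rep(0, 10))
  wB <- c(rep(0, 15), seq(0.2, 1, length.out = 6), seq(0.9, 0.3, length.out = 4))
  ep <- outer(a, wA) + outer(b, wB) # GFP peaks exactly at samples 11 and 21
  expect_identical(findGFPPeaks(computeGFP(ep)$values), c(11L, 21L))
  seg <- backfit(cbind(A = a, B = b), ep)
  lab <- stateLabels(seg)[1, ]
  expect_true(all(lab[1:15] == 1L)) # earlier peak's run ends before the midpoint
  expect_true(all(lab[16:25] == 2L)) # halfway sample belongs to the later peak
  # both runs touch an epoch boundary here, so both are flagged truncated
  expect_true(all(truncatedMask(seg)[1, ]))
})

test_that("peak-mode labels are invariant to uniform scaling of the epochs", {
  tpl <- makeTopographies(16, 3, seed = 18)
  sim <- simulateMicrostateEEG(tpl, 80, 256, 4, snr = 5, seed = 18)
  ep <- epochAndSelect(sim$recording, 2, 2)
  seg1 <- backfit(tpl, ep)
  scaled <- new("EpochSet",
    epochs = epochsArray(ep) * 37.5, fs = samplingRate(ep),
    epochLengthS = 2, channelLabels = channelLabels(ep)
  )
  seg2 <- backfit(tpl, scaled)
  expect_identical(stateLabels(seg1), stateLabels(seg2))
})

test_that("all-samples mode agrees with peak mode away from run boundaries", {
  tpl <- makeTopographies(24, 3, seed = 19)
  sim <- simulateMicrostateEEG(tpl, 120, 256, 4, snr = Inf, seed = 19)
  ep <- epochAndSelect(sim$recording, 2, 2)
  segP <- backfit(tpl, ep, mode = "peaks_interpolated")
  segA <- backfit(tpl, ep, mode = "all_samples")
  for (e in 1:2) {
    lp <- stateLabels(segP)[e, ]
    la <- stateLabels(segA)[e, ]
    ok <- !is.na(la)
    # interior of runs: samples whose two neighbours share their label. Peak
    # mode places boundaries on the GFP-peak grid (50 ms at a 10 Hz carrier)
    # and absorbs runs shorter than the grid entirely, so agreement with the
    # sample-exact mode is high but not perfect even at infinite SNR.
    interior <- which(ok &
      c(FALSE, la[-1] == la[-length(la)]) &
      c(la[-length(la)] == la[-1], FALSE))
    expect_gt(mean(lp[interior] == la[interior]), 0.85)
  }
})

test_that("epochs with fewer than two GFP peaks are skipped with a warning", {
  a <- makeTopographies(16, 1, seed = 20)[, 1]
  ep <- outer(a, seq(0.1, 1, length.out = 50)) # monotone GFP: no peaks
  expect_warning(seg <- backfit(matrix(a), ep), "fewer than 2 GFP peaks")
  expect_true(all(is.na(stateLabels(seg))))
})

test_that("temporal metrics follow the definitional arithmetic", {
  # one epoch at fs 1000: truncated C run, A x4, B x6, truncated C run
  lab <- c(rep(3L, 5), rep(1L, 4), rep(2L, 6), rep(3L, 5))
  tr <- rep(FALSE, 20)
  tr[1:5] <- TRUE
  tr[16:20] <- TRUE
  seg <- new("Segmentation",
    labels = matrix(lab, 1), truncated = matrix(tr, 1),
    fs = 1000, k = 3L, source = "peaks_interpolated", nPeaks = 5L
  )
  expect_warning(m <- temporalMetrics(seg), "no non-truncated runs")
  expect_equal(unname(classDuration(m)[c("A", "B")]), c(4, 6))
  expect_true(is.na(classDuration(m)["C"]))
  expect_equal(unname(classCoverage(m)[c("A", "B")]), c(0.4, 0.6))
  expect_equal(sum(classCoverage(m)), 1)
  expect_equal(meanDuration(m), 5)
  # duration x occurrence = coverage x 1000, per class
  expect_equal(
    unname(classDuration(m) * classOccurrence(m))[1:2],
    unname(1000 * classCoverage(m))[1:2]
  )
})

test_that("coverage partitions analysed time on simulated data", {
  tpl <- makeTopographies(16, 4, seed = 21)
  sim <- simulateMicrostateEEG(tpl, 80, 256, 20, snr = 5, seed = 21)
  ep <- epochAndSelect(sim$recording, 2, 10)
  m <- temporalMetrics(backfit(tpl, ep))
  expect_equal(sum(classCoverage(m)), 1, tolerance = 1e-9)
  expect_true(all(classCoverage(m) >= 0))
  expect_true(all(classOccurrence(m) >= 0))
  expect_equal(
    unname(classDuration(m) * classOccurrence(m)),
    unname(1000 * classCoverage(m)),
    tolerance = 1e-9
  )
})
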
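test_that("TAAHC with k = n gives GEV 1 and rejects k above the map count", {
  set.seed(6)
  maps <- makeTopographies(16, 6, seed = 6)
  fit <- taahc(maps, kMin = 1, kMax = 6)
  expect_equal(gevOf(fit$solutions[["6"]]$model), 1, tolerance = 1e-9)
  expect_error(taahc(maps, kMin = 1, kMax = 7), "exceeds")
})

test_that("TAAHC recovers planted clusters and matches the exhaustive GEV optimum", {
  set.seed(7)
  pg <- plantedThreeGroups(seed = 7)
  fit <- taahc(pg$maps, kMin = 3, kMax = 3, gfpValues = pg$gfp)
  sol <- fit$solutions[["3"]]
  expect_identical(
    canonicalPartition(sol$assignment),
    canonicalPartition(pg$membership)
  )
  # brute force over all partitions of 9 maps into 3 blocks
  parts <- allPartitions(9, 3)
  gevs <- vapply(parts, function(p) partitionGEV(pg$maps, p, pg$gfp), numeric(1))
  best <- parts[[which.max(gevs)]]
  expect_identical(canonicalPartition(sol$assignment), canonicalPartition(best))
  expect_equal(gevOf(sol$model), max(gevs), tolerance = 1e-9)
})

test_that("duplicated maps are always co-clustered", {
  set.seed(8)
  maps <- makeTopographies(16, 5, seed = 8)
  maps <- cbind(maps, maps[, 2]) # duplicate map 2
  fit <- taahc(maps, kMin = 2, kMax = 4)
  for (k in 2:4) {
    a <- fit$solutions[[as.character(k)]]$assignment
    expect_identical(a[2], a[6])
  }
})

test_that("GEV is non-decreasing in k for nested TAAHC solutions", {
  set.seed(9)
  tpl <- makeTopographies(24, 4, seed = 9)
  sim <- simulateMicrostateEEG(tpl, 80, 256, 10, snr = 3, seed = 9)
  ep <- epochAndSelect(sim$recording, 2, 5)
  pm <- gfpPeakMaps(ep)
  fit <- taahc(pm$maps, kMin = 1, kMax = 8, gfpValues = pm$gfp)
  gev <- vapply(as.character(1:8), function(k) gevOf(fit$solutions[[k]]$model), numeric(1))
  expect_true(all(diff(gev) >= -1e-9))
  expect_true(all(gev >= 0 & gev <= 1))
})

test_that("global explained variance follows its definition", {
  set.seed(10)
  tpl <- makeTopographies(16, 3, seed = 10)
  # maps exactly equal to templates -> 1
  expect_equal(globalExplainedVariance(tpl, tpl), 1, tolerance = 1e-12)

  # hand-set: 2 maps, 1 template, equal GFP, correlations 1 and 0 -> 0.5
  a <- tpl[, 1]
  b <- rnorm(16)
  b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a * a)
  b <- b / sqrt(mean(b^2))
  expect_equal(
    globalExplainedVariance(matrix(a), cbind(a, b)),
    0.5,
    tolerance = 1e-12
  )
  # maps orthogonal to all templates -> 0
  expect_lt(globalExplainedVariance(matrix(a), matrix(b)), 1e-12)
  expect_error(globalExplainedVariance(tpl, tpl[, integer(0)]), "empty")
})

test_that("the meta-criterion recovers a planted k and degrades sanely", {
  tpl <- makeTopographies(64, 4, seed = 11)
  sim <- simulateMicrostateEEG(tpl, 80, 256, 30, snr = 8, seed = 11)
  ep <- epochAndSelect(sim$recording, 2, 15)
  pm <- gfpPeakMaps(ep)
  fit <- taahc(pm$maps, kMin = 1, kMax = 12, gfpValues = pm$gfp)
  expect_equal(as.integer(selectOptimalK(fit)), 4L)

  # identical maps only: no structure beyond one class
  one <- makeTopographies(16, 1, seed = 12)
  flat <- one[, rep(1, 30)] * rep(1, 30) # 30 copies
  fitFlat <- taahc(flat, kMin = 1, kMax = 5)
  expect_equal(as.integer(selectOptimalK(fitFlat, kRange = c(1, 5))), 1L)

  expect_error(selectOptimalK(fit, criteria = "cv"), "at least 2")
})
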
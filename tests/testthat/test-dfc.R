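test_that("window arithmetic and degenerate windows behave as specified", {
  set.seed(33)
  x <- matrix(rnorm(5 * 100), 5)
  tcs <- new("NetworkTimecourseSet", data = x, trS = 2, networkNames = paste0("N", 1:5))
  w <- slidingWindowDFC(tcs, 22, 1, 3)
  expect_equal(ncol(w$connectivity), 79L)
  expect_true(all(abs(w$connectivity) <= 1 + 1e-12))

  # identical series -> correlation 1 in every window
  x2 <- rbind(x[1, ], x[1, ], x[2, ])
  tcs2 <- new("NetworkTimecourseSet", data = x2, trS = 2, networkNames = paste0("N", 1:3))
  w2 <- slidingWindowDFC(tcs2, 22, 1, 0)
  expect_true(all(abs(w2$connectivity["N1~N2", ] - 1) < 1e-9))

  # zero-variance segment -> NA, never silently zero
  x3 <- x
  x3[1, 1:40] <- 7
  tcs3 <- new("NetworkTimecourseSet", data = x3, trS = 2, networkNames = paste0("N", 1:5))
  w3 <- slidingWindowDFC(tcs3, 22, 1, 0)
  expect_true(all(is.na(w3$connectivity["N1~N2", 1:10])))

  expect_error(slidingWindowDFC(tcs, 200, 1), "longer than")
  expect_error(slidingWindowDFC(tcs, 22, 0), "step")
})

test_that("a full-length window reproduces the static correlation", {
  set.seed(34)
  x <- matrix(rnorm(4 * 80), 4)
  tcs <- new("NetworkTimecourseSet", data = x, trS = 2, networkNames = paste0("N", 1:4))
  w <- slidingWindowDFC(tcs, 80, 1, 0)
  expect_equal(ncol(w$connectivity), 1L)
  R <- cor(t(x))
  expect_equal(unname(w$connectivity[, 1]), unname(R[w$pairs]), tolerance = 1e-12)
})

test_that("windowed correlations of independent noise match finite-sample theory", {
  set.seed(35)
  x <- matrix(rnorm(2 * 8800), 2)
  tcs <- new("NetworkTimecourseSet", data = x, trS = 2, networkNames = c("N1", "N2"))
  # non-overlapping rectangular windows: independent draws
  w <- slidingWindowDFC(tcs, 22, 22, 0)
  z <- atanh(w$connectivity[1, ])
  expect_lt(abs(mean(z)), 0.05)
  expect_equal(var(z), 1 / (22 - 3), tolerance = 0.35) # Fisher z variance 1/(n-3)
})

test_that("variability summaries respect their preconditions and invariances", {
  set.seed(36)
  sim <- simulateNetworkTimecourses(5, 300, 2, switchingStates(5, 0.8),
    dwellVolumes = 25, seed = 36
  )
  w <- slidingWindowDFC(sim$timecourses)
  v <- dfcVariability(w)
  expect_true(all(pairVariability(v) >= 0))
  expect_length(networkVariability(v), 5L)

  # invariant to per-network affine rescaling
  x <- networkData(sim$timecourses)
  xr <- x * c(2, 0.5, 10, 1, 3) + c(100, -5, 0, 7, 1)
  tcsR <- new("NetworkTimecourseSet", data = xr, trS = 2, networkNames = paste0("N", 1:5))
  vr <- dfcVariability(slidingWindowDFC(tcsR))
  expect_equal(pairVariability(vr), pairVariability(v), tolerance = 1e-9)

  expect_error(
    dfcVariability(slidingWindowDFC(sim$timecourses, 299, 1)),
    "at least 3 windows"
  )
  # constant series: every window undefined -> failure
  flat <- new("NetworkTimecourseSet",
    data = rbind(rep(1, 50), rnorm(50)),
    trS = 2, networkNames = c("N1", "N2")
  )
  expect_error(dfcVariability(slidingWindowDFC(flat, 22, 1, 0)), "undefined")
})

test_that("duration-variability correlations guard their inputs", {
  set.seed(37)
  tab <- data.frame(
    id = paste0("S", 1:10),
    meanDurationMs = seq(60, 100, length.out = 10),
    v1 = rnorm(10), v2 = rnorm(10), const = rep(0.3, 10)
  )
  res <- microstateDfcCorrelation(tab, "meanDurationMs", c("v1", "v2"))
  expect_equal(nrow(res), 2L)
  expect_equal(res$pAdj, p.adjust(res$p, "BH"))
  resB <- microstateDfcCorrelation(tab, "meanDurationMs", c("v1", "v2"),
    adjust = "bonferroni"
  )
  expect_equal(resB$pAdj, pmin(1, resB$p * 2))

  expect_warning(
    resC <- microstateDfcCorrelation(tab, "meanDurationMs", "const"),
    "constant"
  )
  expect_true(is.na(resC$estimate))

  dup <- rbind(tab, tab[1, ])
  expect_error(microstateDfcCorrelation(dup, "meanDurationMs", "v1"), "duplicated")
  expect_error(
    microstateDfcCorrelation(tab[1:3, ], "meanDurationMs", "v1"),
    "fewer than 4"
  )
})
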
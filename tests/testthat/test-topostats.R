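test_that("TANOVA returns 1 for identical maps and detects a planted group shift", {
  C <- 32
  one <- makeTopographies(C, 1, seed = 25)
  arr <- array(rep(one, 4 * 10), c(C, 4, 10))
  grp <- rep(c("a", "b"), each = 5)
  res <- tanova(arr, grp, nPerm = 200, seed = 25)
  expect_true(all(res$p == 1))
  expect_true(all(res$statistic < 1e-12))

  # planted topographic offset in group 2
  set.seed(26)
  base <- makeTopographies(C, 4, seed = 26)
  off <- makeTopographies(C, 1, seed = 27) * 0.8
  arr2 <- array(0, c(C, 4, 10))
  for (s in 1:10) {
    m <- base + matrix(rnorm(C * 4, sd = 0.5), C, 4)
    if (s > 5) m <- m + c(off)
    arr2[, , s] <- m
  }
  res2 <- tanova(arr2, grp, nPerm = 500, seed = 26, effects = "group")
  expect_lt(res2$p["group"], 0.05)
})

test_that("TANOVA p-values are invariant to global scaling of the maps", {
  set.seed(27)
  C <- 16
  arr <- array(rnorm(C * 3 * 8), c(C, 3, 8))
  grp <- rep(c("a", "b"), each = 4)
  r1 <- tanova(arr, grp, nPerm = 200, seed = 5)
  r2 <- tanova(arr * 1e3, grp, nPerm = 200, seed = 5)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-9)
})

test_that("TANOVA rejects malformed inputs", {
  C <- 16
  maps <- lapply(1:4, function(s) matrix(rnorm(C * 3), C, 3))
  maps[[3]] <- maps[[3]][, 1:2] # subject missing a class
  expect_error(tanova(maps, rep(c("a", "b"), 2), nPerm = 100), "mismatched")
  arrNA <- array(NA_real_, c(C, 3, 4))
  expect_error(tanova(arrNA, rep(c("a", "b"), 2), nPerm = 100), "missing")
})

test_that("correlation families are computed pairwise-complete with BH control", {
  set.seed(28)
  n <- 30
  x <- rnorm(n)
  tab <- data.frame(
    x = x,
    mono = exp(2 * x + 1), # monotone transform: spearman rho = 1
    noise1 = rnorm(n), noise2 = rnorm(n), const = rep(1, n)
  )
  res <- correlateWithFDR(tab, "x", c("mono", "noise1", "noise2"), method = "spearman")
  expect_equal(res$estimate[res$y == "mono"], 1)
  # BH adjustment matches the step-up rule and preserves p ordering
  expect_equal(res$pAdj, p.adjust(res$p, "BH"))
  expect_true(all(diff(res$pAdj[order(res$p)]) >= -1e-12))

  expect_warning(
    resC <- correlateWithFDR(tab, "x", c("mono", "const")),
    "constant"
  )
  expect_true(is.na(resC$estimate[resC$y == "const"]))
  expect_error(correlateWithFDR(tab[1:3, ], "x", "mono"), "complete pairs")
})

test_that("BH-controlled families keep false discoveries near the nominal rate", {
  set.seed(29)
  hits <- replicate(200, {
    tab <- as.data.frame(matrix(rnorm(20 * 21), 20))
    names(tab) <- c("y", paste0("v", 1:20))
    res <- correlateWithFDR(tab, "y", paste0("v", 1:20), method = "pearson")
    any(res$pAdj <= 0.05)
  })
  # family-wise false discovery under the global null: P(any) <= alpha
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})
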
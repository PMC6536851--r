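# Internal numeric helpers shared across modules.

# Population SD of each column (spatial SD across channels = GFP).
.colGFP <- function(x) {
  n <- nrow(x)
  sqrt(colMeans(x^2) - colMeans(x)^2)
}

# Average-reference columns (subtract per-column channel mean).
.avgRef <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

# Normalize each column to unit GFP; zero-GFP columns -> error unless allow0.
.unitGFP <- function(x, allow0 = FALSE) {
  g <- .colGFP(x)
  if (any(g == 0)) {
    if (!allow0) stop("cannot normalize a zero-variance (flat) map to unit GFP")
    g[g == 0] <- 1
  }
  sweep(x, 2L, g, "/")
}

# Pearson correlation across channels between columns of a (unit-anything) and
# columns of b, assuming both are average-referenced: reduces to the cosine of
# the GFP-normalized maps, computed as one cross-product.
.mapCorr <- function(a, b) {
  a <- .unitGFP(a)
  b <- .unitGFP(b)
  crossprod(a, b) / nrow(a)
}

# Deterministic sub-seed derivation from a master seed (values < 2^31).
.deriveSeeds <- function(seed, n) {
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.saveRNG <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restoreRNG <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run expr under a local seed without disturbing the caller's RNG stream.
# seed = NULL uses (and advances) the global stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) {
    return(eval.parent(substitute(expr)))
  }
  old <- .saveRNG()
  on.exit(.restoreRNG(old))
  set.seed(seed)
  eval.parent(substitute(expr))
}

.classLetters <- function(k) {
  if (k <= 26L) LETTERS[seq_len(k)] else paste0("C", seq_len(k))
}

.assertScalarNumeric <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name))
  }
  if (positive && x <= 0) stop(sprintf("'%s' must be positive", name))
  invisible(x)
}
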
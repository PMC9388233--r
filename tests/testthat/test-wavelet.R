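# Independent oracle: direct 2x2 block filter bank for one Haar level,
# computed from first principles (sum/difference forms).
haarLevelOracle <- function(x) {
  m <- nrow(x) %/% 2L; n <- ncol(x) %/% 2L
  LL <- LH <- HL <- HH <- matrix(0, m, n)
  for (i in seq_len(m)) for (j in seq_len(n)) {
    blk <- x[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]
    LL[i, j] <- sum(blk) / 2
    HL[i, j] <- (blk[1, 1] - blk[2, 1] + blk[1, 2] - blk[2, 2]) / 2
    LH[i, j] <- (blk[1, 1] + blk[2, 1] - blk[1, 2] - blk[2, 2]) / 2
    HH[i, j] <- (blk[1, 1] - blk[2, 1] - blk[1, 2] + blk[2, 2]) / 2
  }
  list(LL = LL, HL = HL, LH = LH, HH = HH)
}

test_that("a constant slice has exactly zero detail coefficients", {
  p <- waveletDecompose(matrix(3.7, 16, 16), levels = 2L)
  for (j in 1:2) for (b in c("H", "V", "D"))
    expect_identical(max(abs(p@details[[j]][[b]])), 0)
  expect_equal(p@approx, matrix(4 * 3.7, 4, 4))
})

test_that("one Haar level matches the direct 2x2 block filter-bank oracle", {
  set.seed(11)
  x <- matrix(rnorm(64), 8, 8)
  p <- waveletDecompose(x, 1L, "haar")
  o <- haarLevelOracle(x)
  expect_equal(p@approx, o$LL, tolerance = 1e-12)
  expect_equal(p@details[[1L]]$H, o$HL, tolerance = 1e-12)
  expect_equal(p@details[[1L]]$V, o$LH, tolerance = 1e-12)
  expect_equal(p@details[[1L]]$D, o$HH, tolerance = 1e-12)
})

test_that("orthonormal wavelets conserve coefficient energy (Parseval)", {
  set.seed(2)
  for (wv in c("haar", "db2")) {
    x <- matrix(rnorm(256), 16, 16)
    p <- waveletDecompose(x, 2L, wv)
    coefEnergy <- sum(p@approx^2) +
      sum(unlist(lapply(p@details, function(d) sum(d$H^2) + sum(d$V^2) +
                          sum(d$D^2))))
    expect_equal(coefEnergy, sum(x^2), tolerance = 1e-8)
  }
})

test_that("reconstruction inverts decomposition to machine precision", {
  set.seed(5)
  for (wv in c("haar", "db2")) {
    for (shape in list(c(32L, 32L), c(16L, 32L), c(64L, 32L))) {
      x <- matrix(rnorm(prod(shape)), shape[1L], shape[2L])
      for (lv in 1:3) {
        p <- waveletDecompose(x, lv, wv)
        expect_lt(max(abs(waveletReconstruct(p) - x)), 1e-10)
      }
    }
  }
})

test_that("zeroed Haar details reconstruct the 2x2 block means", {
  checker <- outer(1:8, 1:8, function(i, j) (-1)^(i + j))
  p <- waveletDecompose(checker, 1L, "haar")
  p@details[[1L]] <- lapply(p@details[[1L]], function(m) m * 0)
  rec <- waveletReconstruct(p)
  blockMeans <- matrix(0, 8, 8)
  for (i in 1:4) for (j in 1:4)
    blockMeans[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)] <-
      mean(checker[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  expect_equal(rec, blockMeans, tolerance = 1e-12)
})

test_that("an all-zero pyramid reconstructs an all-zero slice", {
  p <- waveletDecompose(matrix(rnorm(64), 8, 8), 1L)
  p@approx <- p@approx * 0
  p@details[[1L]] <- lapply(p@details[[1L]], function(m) m * 0)
  expect_identical(waveletReconstruct(p), matrix(0, 8, 8))
})

test_that("undersized or non-dyadic slices are rejected", {
  expect_error(waveletDecompose(matrix(0, 2, 2), levels = 2L), "small")
  expect_error(waveletDecompose(matrix(0, 6, 6), levels = 2L), "divisible")
  expect_error(waveletDecompose(matrix(0, 8, 8), 1L, "sym9"), "unknown wavelet")
})

test_that("detail vectorization roundtrips through a pyramid", {
  set.seed(9)
  x <- matrix(rnorm(256), 16, 16)
  p <- waveletDecompose(x, 2L)
  v <- BrainSeg3D:::pyramidDetailVector(p)
  p2 <- BrainSeg3D:::pyramidWithDetails(p, v)
  expect_equal(waveletReconstruct(p2), x, tolerance = 1e-12)
  expect_identical(length(v), 16L * 16L - 4L * 4L)
})
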
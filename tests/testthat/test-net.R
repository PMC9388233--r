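# Independent parameter-count oracle from the architecture arithmetic:
# two (k^3*cin+1)*cout conv blocks per level (+2 norm vectors of cout
# when instance norm is on), attention (C+1 spatial + C*(C+1) channel)
# per decoder level, and the (f1+1)*K head.
paramCountOracle <- function(cfg) {
  k3 <- cfg$kernel^3
  normPer <- if (cfg$norm == "instance") 2L else 0L
  block <- function(cin, cout) (k3 * cin + 1L) * cout + normPer * cout
  total <- 0L
  cin <- cfg$inChannels
  for (i in seq_len(cfg$depth)) {
    f <- cfg$baseFilters * 2L^(i - 1L)
    total <- total + block(cin, f) + block(f, f)
    cin <- f
  }
  fb <- cfg$baseFilters * 2L^cfg$depth
  total <- total + block(cin, fb) + block(fb, fb)
  for (i in rev(seq_len(cfg$depth))) {
    f <- cfg$baseFilters * 2L^(i - 1L)
    ccat <- 3L * f
    total <- total + (ccat + 1L) + ccat * (ccat + 1L)   # attention gates
    total <- total + block(ccat, f) + block(f, f)
  }
  total + (cfg$baseFilters + 1L) * cfg$outClasses
}

test_that("attention with zero maps is exactly the identity (bypass path)", {
  set.seed(40)
  x <- array(rnorm(4^3 * 3), c(4L, 4L, 4L, 3L))
  out <- attentionApply(x, array(0, c(4L, 4L, 4L)), numeric(3L))
  expect_identical(out, x)
})

test_that("attention module output matches a stepwise manual composition", {
  set.seed(41)
  x <- array(rnorm(4^3 * 2), c(4L, 4L, 4L, 2L))
  wts <- list(sw = matrix(c(0.3, -0.2), 2L, 1L), sb = 0.1,
              cw = matrix(c(0.5, -0.1, 0.2, 0.4), 2L, 2L),
              cb = c(-0.2, 0.3))
  res <- attentionForward(x, wts)
  # manual composition, voxel by voxel
  sig <- function(v) 1 / (1 + exp(-v))
  manual <- array(0, dim(x))
  pool <- c(mean(x[, , , 1L]), mean(x[, , , 2L]))
  cg <- sig(as.numeric(t(wts$cw) %*% pool) + wts$cb)
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    v <- x[i, j, k, ]
    s <- sig(sum(v * wts$sw[, 1L]) + wts$sb)
    manual[i, j, k, ] <- v + v * s * cg
  }
  expect_equal(res$out, manual, tolerance = 1e-6)
  expect_true(all(res$maps$spatial > 0 & res$maps$spatial < 1))
  expect_true(all(res$maps$channel > 0 & res$maps$channel < 1))
  expect_identical(dim(res$out), dim(x))
  expect_error(attentionForward(x * NaN, wts), "non-finite")
})

test_that("parameter count matches the independent architecture formula", {
  for (cfg in list(unetConfig(depth = 2L, baseFilters = 4L,
                              inChannels = 5L, outClasses = 4L),
                   unetConfig(depth = 3L, baseFilters = 8L),
                   unetConfig(depth = 1L, baseFilters = 6L,
                              norm = "none", outClasses = 2L))) {
    m <- buildModel(cfg, seed = 0L)
    expect_identical(nParams(m), as.integer(paramCountOracle(cfg)))
  }
})

test_that("forward preserves spatial shape with one score per class", {
  m <- buildModel(unetConfig(depth = 2L, baseFilters = 4L), seed = 0L)
  x <- array(rnorm(16 * 8 * 12 * 5), c(16L, 8L, 12L, 5L))
  fw <- BrainSeg3D:::netForward(m, x)
  pr <- array(BrainSeg3D:::.softmaxRows(fw$logits2), c(16L, 8L, 12L, 4L))
  expect_identical(dim(pr), c(16L, 8L, 12L, 4L))
  expect_equal(apply(pr, 1:3, sum), array(1, c(16L, 8L, 12L)),
               tolerance = 1e-12)
  expect_error(BrainSeg3D:::netForward(m, x[1:15, , , , drop = FALSE]),
               "divisible")
})

test_that("two builds with the same seed share identical initial weights", {
  a <- buildModel(unetConfig(), seed = 5L)
  b <- buildModel(unetConfig(), seed = 5L)
  expect_identical(a$params, b$params)
  c2 <- buildModel(unetConfig(), seed = 6L)
  expect_false(identical(a$params, c2$params))
})

test_that("every parameter tensor receives gradient (no dead branches)", {
  set.seed(43)
  m <- buildModel(unetConfig(depth = 2L, baseFilters = 4L), seed = 1L)
  x <- array(rnorm(8^3 * 5), c(8L, 8L, 8L, 5L))
  y <- sample.int(4L, 8^3, replace = TRUE)
  fw <- BrainSeg3D:::netForward(m, x)
  ls <- BrainSeg3D:::segLoss(fw$logits2, y)
  gr <- BrainSeg3D:::netBackward(m, fw, ls$grad)
  norms <- vapply(names(m$params),
                  function(nm) sqrt(sum(gr[[nm]]^2)), numeric(1L))
  expect_true(all(norms > 0))
})

test_that("sliding-window inference is deterministic and label-closed", {
  m <- buildModel(unetConfig(depth = 2L, baseFilters = 4L), seed = 2L)
  set.seed(44)
  x <- array(rnorm(16^3 * 5), c(16L, 16L, 16L, 5L))
  m1 <- segmentVolume(m, x, patchSize = 16L)
  m2 <- segmentVolume(m, x, patchSize = 16L)
  expect_identical(maskLabels(m1), maskLabels(m2))
  expect_true(all(unique(as.vector(maskLabels(m1))) %in% c(0L, 1L, 2L, 4L)))
})

test_that("overlap averaging leaves a constant-prediction model unchanged", {
  cfg <- unetConfig(depth = 2L, baseFilters = 4L)
  m <- buildModel(cfg, seed = 3L)
  # force constant output: zero every weight, fix head bias
  m$params <- lapply(m$params, function(p) p * 0)
  m$params$head_b <- c(0.1, 1.5, 0.2, 0.3)
  set.seed(45)
  x <- array(rnorm(24^3 * 5), c(24L, 24L, 24L, 5L))
  whole <- segmentVolume(m, x, patchSize = 24L)
  tiled <- segmentVolume(m, x, patchSize = 12L, overlap = 0.5)
  expect_identical(maskLabels(whole), maskLabels(tiled))
  expect_true(all(maskLabels(whole) == 1L))
})

test_that("channel mismatches are rejected at the config surface", {
  m <- buildModel(unetConfig(inChannels = 5L), seed = 0L)
  x <- array(0, c(8L, 8L, 8L, 3L))
  expect_error(BrainSeg3D:::netForward(m, x), "5")
  expect_error(segmentVolume(m, array(0, c(8L, 8L, 8L, 5L)),
                             labelSet = c(1L, 2L)), "outClasses")
})
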
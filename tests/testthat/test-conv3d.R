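# Naive triple-loop oracle, written independently of the implementation.
conv3dLoopOracle <- function(input, weights) {
  di <- dim(input); dw <- dim(weights)
  od <- di - dw + 1L
  out <- array(0, od)
  for (i in seq_len(od[1L])) for (j in seq_len(od[2L]))
    for (k in seq_len(od[3L])) {
      s <- 0
      for (a in seq_len(dw[1L])) for (b in seq_len(dw[2L]))
        for (cc in seq_len(dw[3L]))
          s <- s + weights[a, b, cc] *
            input[i + a - 1L, j + b - 1L, k + cc - 1L]
      out[i, j, k] <- s
    }
  out
}

test_that("a delta kernel crops the input to the valid region", {
  set.seed(30)
  y <- array(rnorm(5^3), c(5L, 5L, 5L))
  w <- array(0, c(2L, 2L, 2L)); w[1L, 1L, 1L] <- 1
  fw <- conv3dForward(y, w)
  expect_equal(fw$out, y[1:4, 1:4, 1:4])
})

test_that("counting check: all-ones input and 2^3 kernel gives 8 everywhere", {
  fw <- conv3dForward(array(1, c(4L, 4L, 4L)), array(1, c(2L, 2L, 2L)))
  expect_equal(fw$out, array(8, c(3L, 3L, 3L)))
})

test_that("forward matches the naive triple-loop oracle", {
  set.seed(31)
  y <- array(rnorm(5^3), c(5L, 5L, 5L))
  w <- array(rnorm(27), c(3L, 3L, 3L))
  expect_lt(max(abs(conv3dForward(y, w)$pre - conv3dLoopOracle(y, w))),
            1e-12)
  expect_error(conv3dForward(array(0, c(2L, 2L, 2L)), w), "larger")
})

test_that("weight gradient: zero upstream and single-term cases", {
  set.seed(32)
  y <- array(rnorm(6^3), c(6L, 6L, 6L))
  gz <- array(0, c(4L, 4L, 4L))
  expect_equal(conv3dBackwardWeights(gz, y), array(0, c(3L, 3L, 3L)))
  g1 <- gz; g1[1L, 1L, 1L] <- 1
  expect_equal(conv3dBackwardWeights(g1, y), y[1:3, 1:3, 1:3])
})

test_that("both backward passes match central finite differences", {
  for (actv in c("identity", "sigmoid", "relu")) {
    gcr <- gradientCheck(6L, 3L, actv, seed = 0L)
    expect_lt(gcr$weightsVsFD, 1e-5)
    expect_lt(gcr$inputVsFD, 1e-5)
  }
})

test_that("reference gradients agree with the network conv layer's backward", {
  for (seed in 0:2) {
    gcr <- gradientCheck(6L, 3L, "sigmoid", seed = seed)
    expect_lt(gcr$weightsVsNet, 1e-6)
    expect_lt(gcr$inputVsNet, 1e-6)
  }
})

test_that("gradient check reports are reproducible for a fixed seed", {
  a <- gradientCheck(5L, 2L, "relu", seed = 7L)
  b <- gradientCheck(5L, 2L, "relu", seed = 7L)
  expect_identical(a, b)
})

test_that("input gradient: delta kernel zero-pads; backward is linear", {
  set.seed(33)
  g <- array(rnorm(4^3), c(4L, 4L, 4L))
  w0 <- array(0, c(3L, 3L, 3L)); w0[1L, 1L, 1L] <- 1
  gy <- conv3dBackwardInput(g, w0)
  expect_equal(gy[1:4, 1:4, 1:4], g)
  expect_equal(sum(abs(gy)) - sum(abs(g)), 0)
  w <- array(rnorm(27), c(3L, 3L, 3L))
  y <- array(rnorm(6^3), c(6L, 6L, 6L))
  expect_equal(conv3dBackwardInput(3 * g, w), 3 * conv3dBackwardInput(g, w))
  expect_equal(conv3dBackwardWeights(3 * g, y),
               3 * conv3dBackwardWeights(g, y), tolerance = 1e-12)
})

test_that("adjoint identity <conv(y, w), g> = <y, backward_input(g, w)>", {
  set.seed(34)
  for (rep in 1:5) {
    y <- array(rnorm(6^3), c(6L, 6L, 6L))
    w <- array(rnorm(27), c(3L, 3L, 3L))
    g <- array(rnorm(4^3), c(4L, 4L, 4L))
    lhs <- sum(conv3dForward(y, w)$pre * g)
    rhs <- sum(y * conv3dBackwardInput(g, w))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("activation backward applies the derivative elementwise", {
  g <- array(2, c(3L, 3L, 3L))
  pre <- array(0, c(3L, 3L, 3L))
  expect_equal(activationBackward(g, pre, "identity"), g)
  expect_equal(activationBackward(g, pre, "sigmoid"), g * 0.25)
  set.seed(35)
  preR <- array(rnorm(27), c(3L, 3L, 3L))
  gr <- activationBackward(g, preR, "relu")
  expect_true(all(gr[preR < 0] == 0))
  expect_true(all(gr[preR > 0] == 2))
  expect_error(activationBackward(array(0, c(2L, 2L, 2L)), pre), "mismatch")
})
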
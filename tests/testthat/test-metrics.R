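test_that("region masks respect the nesting WT >= TC >= ET", {
  z <- SegmentationMask(array(0L, c(4L, 4L, 4L)))
  r <- regionMasks(z)
  expect_true(all(!r$ET & !r$TC & !r$WT))

  one <- placeLabels(c(4L, 4L, 4L), cbind(2L, 2L, 2L), 4L)
  r1 <- regionMasks(SegmentationMask(one))
  expect_true(r1$ET[2L, 2L, 2L] && r1$TC[2L, 2L, 2L] && r1$WT[2L, 2L, 2L])

  set.seed(50)
  rnd <- array(sample(c(0L, 1L, 2L, 4L), 6^3, replace = TRUE), c(6L, 6L, 6L))
  rr <- regionMasks(SegmentationMask(rnd))
  # brute-force set comparison on voxel index sets
  expect_true(all(which(rr$ET) %in% which(rr$TC)))
  expect_true(all(which(rr$TC) %in% which(rr$WT)))
  expect_identical(which(rr$WT), which(rnd %in% c(1L, 2L, 4L)))
})

test_that("Dice: identical, disjoint and hand-counted overlaps", {
  a <- array(FALSE, c(4L, 4L, 4L)); a[1:2, 1L, 1L] <- TRUE
  expect_equal(diceCoefficient(a, a), 1)
  b <- array(FALSE, c(4L, 4L, 4L)); b[4L, 4L, 4L] <- TRUE
  expect_equal(diceCoefficient(a, b), 0)
  # |A| = 4, |B| = 2, overlap 2 -> 2*2/(4+2)
  A <- array(FALSE, c(4L, 4L, 4L)); A[1:4, 1L, 1L] <- TRUE
  B <- array(FALSE, c(4L, 4L, 4L)); B[1:2, 1L, 1L] <- TRUE
  expect_equal(diceCoefficient(A, B), 2 * 2 / (4 + 2), tolerance = 1e-12)
  expect_equal(diceCoefficient(A, B), diceCoefficient(B, A))
  empty <- array(FALSE, c(4L, 4L, 4L))
  expect_equal(diceCoefficient(empty, empty), 1)
  expect_error(diceCoefficient(A, array(FALSE, c(3L, 3L, 3L))), "mismatch")
})

test_that("Hausdorff: geometry cases and spacing", {
  a <- array(FALSE, c(8L, 8L, 8L)); a[2:4, 2:4, 2:4] <- TRUE
  expect_equal(hausdorffDistance(a, a), 0)
  p1 <- placeLabels(c(8L, 8L, 8L), cbind(2L, 2L, 2L), 1L) > 0L
  p2 <- placeLabels(c(8L, 8L, 8L), cbind(5L, 2L, 2L), 1L) > 0L
  expect_equal(hausdorffDistance(p1, p2, percentile = 100), 3)
  expect_equal(hausdorffDistance(p1, p2, spacing = c(2, 1, 1),
                                 percentile = 100), 6)
  expect_warning(hp <- hausdorffDistance(p1, array(FALSE, c(8L, 8L, 8L))),
                 "empty")
  expect_gt(hp, 0)
  expect_equal(hausdorffDistance(array(FALSE, c(8L, 8L, 8L)),
                                 array(FALSE, c(8L, 8L, 8L))), 0)
})

test_that("Hausdorff matches the exhaustive all-pairs oracle on small masks", {
  set.seed(51)
  for (rep in 1:5) {
    a <- array(runif(6^3) < 0.25, c(6L, 6L, 6L))
    b <- array(runif(6^3) < 0.25, c(6L, 6L, 6L))
    if (sum(a) == 0L || sum(b) == 0L) next
    sp <- c(1, 1.5, 2)
    expect_equal(hausdorffDistance(a, b, spacing = sp),
                 bruteHausdorff(a, b, spacing = sp), tolerance = 1e-12)
  }
})

test_that("sensitivity/specificity from printed counts TP=3 FN=1 TN=5 FP=1", {
  # 10 voxels: truth has 4 positives; prediction hits 3, adds 1 false alarm
  truth <- array(c(rep(TRUE, 4L), rep(FALSE, 6L)), c(10L, 1L, 1L))
  pred <- array(c(rep(TRUE, 3L), FALSE, TRUE, rep(FALSE, 5L)),
                c(10L, 1L, 1L))
  ss <- sensitivitySpecificity(pred, truth)
  expect_equal(ss[["sensitivity"]], 0.75)
  expect_equal(ss[["specificity"]], 5 / 6, tolerance = 1e-4)
  perfect <- sensitivitySpecificity(truth, truth)
  expect_equal(unname(perfect), c(1, 1))
  allBg <- array(FALSE, dim(truth))
  expect_equal(sensitivitySpecificity(allBg, truth)[["sensitivity"]], 0)
  expect_warning(sensitivitySpecificity(allBg, allBg), "undefined")
})

test_that("pixel confusion reproduces the printed 809x974 tumor accounting", {
  truth <- array(FALSE, c(809L, 974L, 1L))
  truth[seq_len(853L)] <- TRUE
  pc <- pixelConfusion(truth, truth)
  expect_identical(pc$tp, 853L)
  expect_identical(pc$tn, 787113L)
  expect_identical(pc$tp + pc$fp + pc$fn + pc$tn, 809L * 974L)
  expect_equal(pc$accuracy, 1)
})

test_that("pixel confusion matches a brute-force per-pixel tally", {
  set.seed(52)
  p <- array(runif(100) < 0.4, c(10L, 10L, 1L))
  g <- array(runif(100) < 0.4, c(10L, 10L, 1L))
  pc <- pixelConfusion(p, g)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(p)) {
    if (p[i] && g[i]) tp <- tp + 1L
    else if (p[i] && !g[i]) fp <- fp + 1L
    else if (!p[i] && g[i]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  expect_identical(c(pc$tp, pc$fp, pc$fn, pc$tn), c(tp, fp, fn, tn))
  expect_equal(pc$precision, tp / (tp + fp))
  expect_equal(pc$recall, tp / (tp + fn))
})

test_that("an oracle prediction hits the metric fixed points in all regions", {
  ph <- generatePhantom(tinyPhantomConfig(shape = c(24L, 24L, 24L)), 1L)
  res <- evaluateCase(ph$mask, ph$mask)
  expect_equal(res$regions$dice, rep(1, 3L))
  expect_equal(res$regions$hausdorff, rep(0, 3L))
  expect_equal(res$regions$sensitivity, rep(1, 3L))
  expect_equal(res$regions$specificity, rep(1, 3L))
  expect_identical(res$confusion$fp + res$confusion$fn, 0L)
})

test_that("empty-in-both ET falls back to Dice 1 by convention", {
  lab <- placeLabels(c(6L, 6L, 6L), cbind(3L, 3L, 3L), 2L)  # edema only
  m <- SegmentationMask(lab)
  res <- evaluateCase(m, m)
  expect_equal(res$regions$dice[res$regions$region == "ET"], 1)
})

test_that("aggregation matches hand arithmetic and ignores case order", {
  mk <- function(d) list(regions = data.frame(
    region = c("ET", "TC", "WT"), dice = d, hausdorff = 1 - d,
    sensitivity = d, specificity = d))
  cases <- list(mk(c(0.5, 0.6, 0.7)), mk(c(0.7, 0.8, 0.9)),
                mk(c(0.6, 0.7, 0.8)))
  agg <- aggregateMetrics(cases)
  et <- agg[agg$region == "ET" & agg$metric == "dice", ]
  expect_equal(et$mean, 0.6)
  expect_equal(et$stddev, sd(c(0.5, 0.7, 0.6)))
  expect_equal(et$median, 0.6)
  aggRev <- aggregateMetrics(rev(cases))
  expect_equal(agg, aggRev)
})
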
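test_that("NIfTI write/read roundtrips volumes exactly at stored precision", {
  tmp <- withr::local_tempdir()
  a <- array(5, c(5L, 5L, 5L))
  aff <- diag(4); aff[1:3, 4] <- c(-10, 5, 2)
  f <- file.path(tmp, "const.nii.gz")
  writeVolume(a, f, affine = aff)
  rt <- readVolume(f)
  expect_identical(rt$data, a)
  expect_equal(rt$affine, aff)

  set.seed(7)
  b <- array(rnorm(6 * 4 * 8), c(6L, 4L, 8L))
  f2 <- file.path(tmp, "rand.nii.gz")
  writeVolume(b, f2)
  expect_equal(max(abs(readVolume(f2)$data - b)), 0)
})

test_that("a BraTS-sized modality file reads back with shape 240x240x155", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "brats_sized.nii.gz")
  writeVolume(array(0, c(240L, 240L, 155L)), f, spacing = c(1, 1, 1))
  rt <- readVolume(f)
  expect_identical(dim(rt$data), c(240L, 240L, 155L))
})

test_that("readVolume rejects missing files, non-3D images and NaN voxels", {
  tmp <- withr::local_tempdir()
  expect_error(readVolume(file.path(tmp, "nope.nii")), "not found")

  f4 <- file.path(tmp, "fourd.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f4)
  expect_error(readVolume(f4), "3D")

  fn <- file.path(tmp, "nan.nii.gz")
  a <- array(1, c(4, 4, 4)); a[1] <- NaN
  RNifti::writeNifti(RNifti::asNifti(a), fn)
  expect_error(readVolume(fn), "non-finite")
  expect_equal(readVolume(fn, nonFinite = "zero")$data[1], 0)
})

test_that("mask write/read preserves integer labels and histogram", {
  tmp <- withr::local_tempdir()
  z <- SegmentationMask(array(0L, c(10L, 10L, 10L)))
  f <- file.path(tmp, "zeros.nii.gz")
  writeMask(z, f)
  expect_identical(as.integer(readVolume(f)$data), rep(0L, 1000L))

  ph <- generatePhantom(tinyPhantomConfig(seed = 3L), 1L)
  f2 <- file.path(tmp, "phantom_seg.nii.gz")
  writeMask(ph$mask, f2)
  back <- readVolume(f2)$data
  expect_identical(table(as.integer(back)), table(as.vector(maskLabels(ph$mask))))
  # on-disk dtype is an integer NIfTI code, not float
  hdr <- RNifti::niftiHeader(RNifti::readNifti(f2))
  expect_true(hdr$datatype %in% c(2L, 4L, 8L, 256L, 512L, 768L))
})

test_that("loadCase assembles channels in fixed modality order", {
  tmp <- withr::local_tempdir()
  dirs <- generateDataset(tinyPhantomConfig(shape = c(16L, 16L, 16L),
                                            nCases = 1L), tmp)
  case <- loadCase(dirs[1L])
  expect_s4_class(case$volume, "MultiModalVolume")
  expect_identical(dim(case$volume), c(4L, 16L, 16L, 16L))
  expect_identical(volChannels(case$volume), c("flair", "t1", "t1ce", "t2"))
  expect_s4_class(case$mask, "SegmentationMask")

  # channel assignment comes from filename patterns, not listing order:
  # the t1ce file content must land in channel 3
  t1ce <- readVolume(list.files(dirs[1L], "_t1ce\\.", full.names = TRUE))
  expect_equal(volData(case$volume)[3L, , , ], t1ce$data)
})

test_that("loadCase reports missing modalities and tolerates absent masks", {
  tmp <- withr::local_tempdir()
  dirs <- generateDataset(tinyPhantomConfig(shape = c(16L, 16L, 16L),
                                            nCases = 1L), tmp)
  segFile <- list.files(dirs[1L], "_seg", full.names = TRUE)
  file.remove(segFile)
  case <- loadCase(dirs[1L])
  expect_null(case$mask)

  t2File <- list.files(dirs[1L], "_t2\\.", full.names = TRUE)
  file.remove(t2File)
  expect_error(loadCase(dirs[1L]), "t2")
})

test_that("loadCase rejects masks with labels outside the label set", {
  tmp <- withr::local_tempdir()
  dirs <- generateDataset(tinyPhantomConfig(shape = c(16L, 16L, 16L),
                                            nCases = 1L), tmp)
  segFile <- list.files(dirs[1L], "_seg", full.names = TRUE)
  seg <- readVolume(segFile)
  bad <- seg$data
  bad[1, 1, 1] <- 7
  writeVolume(bad, segFile, affine = seg$affine, spacing = seg$spacing,
              datatype = "int32")
  expect_error(loadCase(dirs[1L]), "7")
})

test_that("the variant label set {1,3,4} maps regions analogously", {
  rm <- defaultRegionMap(c(1L, 3L, 4L))
  expect_identical(rm$ET, 4L)
  expect_identical(sort(rm$TC), c(1L, 4L))
  expect_identical(sort(rm$WT), c(1L, 3L, 4L))
  expect_error(defaultRegionMap(c(2L, 5L)), "no default region mapping")
})
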
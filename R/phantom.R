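# Synthetic multimodal brain phantom in the BraTS case layout: a smooth
# brain ellipsoid containing three nested tumor ellipsoids (edema > core >
# enhancing) with modality-dependent contrasts and additive Gaussian
# noise.  Geometry is deliberately simple; the point is a known ground
# truth for every pipeline stage, not MR realism.

#' Default per-modality region intensities for phantoms
#'
#' Arbitrary intensity units.  Contrasts follow the qualitative BraTS
#' pattern: edema bright on Flair/T2, enhancing tumor bright on T1ce,
#' core dark on T1.
#' @return 4 x 5 numeric matrix (modalities x regions).
#' @export
phantomIntensities <- function() {
  m <- rbind(
    flair = c(0, 100, 160, 130, 140),
    t1    = c(0, 100,  90,  60, 110),
    t1ce  = c(0, 100,  95,  70, 160),
    t2    = c(0, 100, 150, 120, 130)
  )
  colnames(m) <- c("background", "brain", "edema", "core", "enhancing")
  m
}

#' Phantom generator configuration
#'
#' @param shape volume dimensions in voxels (default 64^3; set
#'   \code{c(240, 240, 155)} to mirror full BraTS dimensions).
#' @param nCases number of cases for \code{\link{generateDataset}}.
#' @param labelSet non-zero mask labels; the enhancing ellipsoid gets
#'   label 4, the core label 1, the edema shell the remaining label
#'   (2 under the BraTS convention, 3 under the variant set).
#' @param radiusEdema,radiusCore,radiusEnhancing semi-axis sampling
#'   ranges in voxels; the ranges must be ordered (enhancing < core <
#'   edema) so the subregions nest.  The defaults (10--14, 6--9 and
#'   3--5 voxels) suit the default 64^3 volume; pass scaled ranges for
#'   much smaller or larger grids.
#' @param brainFrac brain-ellipsoid semi-axes as a fraction of the
#'   volume shape.
#' @param intensities modality x region intensity matrix
#'   (\code{\link{phantomIntensities}}).
#' @param noiseSigma additive Gaussian noise s.d., about 5% of the
#'   tumor-tissue contrast at the defaults.
#' @param spacing voxel spacing in mm.
#' @param seed base seed; case \code{i} is fully determined by
#'   \code{(seed, i)}.
#' @return named list of class \code{"phantomConfig"}.
#' @export
phantomConfig <- function(shape = c(64L, 64L, 64L), nCases = 10L,
                          labelSet = c(1L, 2L, 4L),
                          radiusEdema = c(10, 14), radiusCore = c(6, 9),
                          radiusEnhancing = c(3, 5), brainFrac = 0.42,
                          intensities = phantomIntensities(),
                          noiseSigma = 3, spacing = c(1, 1, 1),
                          seed = 0L) {
  stopifnot(noiseSigma >= 0, all(is.finite(intensities)))
  if (max(radiusEnhancing) > min(radiusCore) ||
      max(radiusCore) > min(radiusEdema))
    stop("radius ranges must nest: enhancing < core < edema")
  structure(list(shape = as.integer(shape), nCases = as.integer(nCases),
                 labelSet = as.integer(labelSet),
                 radiusEdema = radiusEdema, radiusCore = radiusCore,
                 radiusEnhancing = radiusEnhancing, brainFrac = brainFrac,
                 intensities = intensities, noiseSigma = noiseSigma,
                 spacing = spacing, seed = as.integer(seed)),
            class = "phantomConfig")
}

.ellipsoidQ <- function(shape, center, semi) {
  gx <- (seq_len(shape[1L]) - center[1L]) / semi[1L]
  gy <- (seq_len(shape[2L]) - center[2L]) / semi[2L]
  gz <- (seq_len(shape[3L]) - center[3L]) / semi[3L]
  outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
}

.ellipsoidMask <- function(shape, center, semi) {
  .ellipsoidQ(shape, center, semi) <= 1
}

#' Generate one synthetic multimodal phantom case
#'
#' Fully determined by \code{(config$seed, caseIndex)}.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param caseIndex positive case number.
#' @return list with \code{volume} (\linkS4class{MultiModalVolume}),
#'   \code{mask} (\linkS4class{SegmentationMask}) and \code{geometry}
#'   (sampled center and semi-axes, for oracle checks).
#' @export
generatePhantom <- function(config, caseIndex = 1L) {
  stopifnot(inherits(config, "phantomConfig"))
  set.seed((config$seed * 1000L + as.integer(caseIndex)) %% 2147483647L)
  shape <- config$shape
  bc <- (shape + 1) / 2
  bsemi <- config$brainFrac * shape
  maxEd <- max(config$radiusEdema)
  room <- bsemi - maxEd - 1
  if (any(room <= 0))
    stop("volume shape too small for the configured tumor radii")
  center <- bc + runif(3L, -1, 1) * room * 0.8
  rEd <- runif(3L, config$radiusEdema[1L], config$radiusEdema[2L])
  rCo <- runif(3L, config$radiusCore[1L], config$radiusCore[2L])
  rEn <- runif(3L, config$radiusEnhancing[1L], config$radiusEnhancing[2L])

  qBrain <- .ellipsoidQ(shape, bc, bsemi)
  # smooth tissue profile: logistic rolloff over a couple of voxels at
  # the brain surface (tumor boundaries stay sharp)
  wBrain <- 1 / (1 + exp((qBrain - 1) / 0.08))
  edema <- .ellipsoidMask(shape, center, rEd)
  core <- .ellipsoidMask(shape, center, rCo)
  enh <- .ellipsoidMask(shape, center, rEn)

  # region code: 1 bg, 2 brain, 3 edema, 4 core, 5 enhancing
  region <- array(1L, shape)
  region[qBrain <= 1] <- 2L
  region[edema] <- 3L
  region[core] <- 4L
  region[enh] <- 5L

  labelEdema <- setdiff(config$labelSet, c(1L, 4L))[1L]
  labels <- array(0L, shape)
  labels[region == 3L] <- labelEdema
  labels[region == 4L] <- 1L
  labels[region == 5L] <- 4L

  ints <- config$intensities
  data <- array(0, c(4L, shape))
  tumor <- region >= 3L
  for (m in 1:4) {
    ch <- ints[m, "background"] +
      (ints[m, "brain"] - ints[m, "background"]) * wBrain
    ch[tumor] <- ints[m, region[tumor]]
    ch <- ch + rnorm(prod(shape), 0, config$noiseSigma)
    data[m, , , ] <- ch
  }
  vol <- MultiModalVolume(data, channels = rownames(ints),
                          spacing = config$spacing)
  mask <- SegmentationMask(labels, labelSet = config$labelSet,
                           spacing = config$spacing)
  list(volume = vol, mask = mask,
       geometry = list(center = center, edema = rEd, core = rCo,
                       enhancing = rEn))
}

#' Write a synthetic dataset in the BraTS case layout
#'
#' Creates \code{nCases} case directories, each with the four modality
#' NIfTI files plus a segmentation file, loadable by
#' \code{\link{loadCase}}, and a JSON manifest recording the generator
#' settings so the dataset can be regenerated bit-for-bit.
#'
#' @param config a \code{\link{phantomConfig}}.
#' @param outDir output directory (created if missing).
#' @return character vector of case directories, invisibly.
#' @export
generateDataset <- function(config, outDir) {
  stopifnot(inherits(config, "phantomConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  caseDirs <- character(config$nCases)
  for (i in seq_len(config$nCases)) {
    id <- sprintf("phantom_%03d", i)
    cd <- file.path(outDir, id)
    dir.create(cd, showWarnings = FALSE)
    ph <- generatePhantom(config, i)
    aff <- volAffine(ph$volume)
    sp <- volSpacing(ph$volume)
    chans <- volChannels(ph$volume)
    for (m in seq_along(chans))
      writeVolume(volData(ph$volume)[m, , , ],
                  file.path(cd, sprintf("%s_%s.nii.gz", id, chans[m])),
                  affine = aff, spacing = sp)
    writeMask(ph$mask, file.path(cd, sprintf("%s_seg.nii.gz", id)))
    caseDirs[i] <- cd
  }
  manifest <- list(
    generator = "BrainSeg3D phantom", shape = config$shape,
    nCases = config$nCases, labelSet = config$labelSet,
    noiseSigma = config$noiseSigma, seed = config$seed,
    caseSeeds = (config$seed * 1000L + seq_len(config$nCases)) %%
      2147483647L
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(caseDirs)
}
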
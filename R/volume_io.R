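#' Construct a MultiModalVolume
#'
#' @param data 4D numeric array \code{(C, X, Y, Z)} or a list of C equally
#'   shaped 3D arrays.
#' @param channels channel names; defaults to the BraTS modality order
#'   \code{c("flair", "t1", "t1ce", "t2")} when C = 4.
#' @param spacing voxel size in mm (length 3).
#' @param affine 4x4 voxel-to-world matrix.
#' @return A validated \linkS4class{MultiModalVolume}.
#' @export
MultiModalVolume <- function(data, channels = NULL, spacing = c(1, 1, 1),
                             affine = diag(4)) {
  if (is.list(data)) {
    shp <- dim(data[[1L]])
    arr <- array(0, c(length(data), shp))
    for (i in seq_along(data)) {
      if (!all(dim(data[[i]]) == shp))
        stop("all channels must share one shape")
      arr[i, , , ] <- data[[i]]
    }
    if (is.null(channels)) channels <- names(data)
    data <- arr
  }
  if (is.null(channels)) {
    channels <- if (dim(data)[1L] == 4L) c("flair", "t1", "t1ce", "t2")
                else sprintf("ch%d", seq_len(dim(data)[1L]))
  }
  new("MultiModalVolume", data = data, channels = channels,
      spacing = as.numeric(spacing), affine = affine)
}

#' Construct a SegmentationMask
#'
#' @param labels 3D integer array (background 0).
#' @param labelSet permitted non-zero labels; default BraTS \code{c(1, 2, 4)}.
#' @param regionMap named list \code{ET}/\code{TC}/\code{WT} of label
#'   subsets; defaults to the conventional mapping for the given label set
#'   (see \code{\link{defaultRegionMap}}).
#' @param spacing,affine geometry metadata.
#' @return A validated \linkS4class{SegmentationMask}.
#' @export
SegmentationMask <- function(labels, labelSet = c(1L, 2L, 4L),
                             regionMap = NULL, spacing = c(1, 1, 1),
                             affine = diag(4)) {
  storage.mode(labels) <- "integer"
  labelSet <- as.integer(labelSet)
  if (is.null(regionMap)) regionMap <- defaultRegionMap(labelSet)
  new("SegmentationMask", labels = labels, labelSet = labelSet,
      regionMap = regionMap, spacing = as.numeric(spacing), affine = affine)
}

#' Default ET/TC/WT region mapping for a label set
#'
#' Under the BraTS convention (\code{labelSet = c(1, 2, 4)}) label 1 is the
#' necrotic/non-enhancing core, 2 the peritumoral edema and 4 the enhancing
#' tumor, giving ET = \{4\}, TC = \{1, 4\}, WT = \{1, 2, 4\}.  The variant
#' label set \code{c(1, 3, 4)} (with 3 playing the edema role) is mapped
#' analogously.
#'
#' @param labelSet integer vector of non-zero labels.
#' @return Named list with elements \code{ET}, \code{TC}, \code{WT}.
#' @export
defaultRegionMap <- function(labelSet) {
  labelSet <- as.integer(labelSet)
  if (setequal(labelSet, c(1L, 2L, 4L)))
    return(list(ET = 4L, TC = c(1L, 4L), WT = c(1L, 2L, 4L)))
  if (setequal(labelSet, c(1L, 3L, 4L)))
    return(list(ET = 4L, TC = c(1L, 4L), WT = c(1L, 3L, 4L)))
  stop("no default region mapping for label set {",
       paste(labelSet, collapse = ", "),
       "}; supply regionMap explicitly")
}

#' Read a 3D NIfTI volume
#'
#' @param path path to a NIfTI-1 file (.nii or .nii.gz).
#' @param nonFinite what to do with NaN/Inf voxels: \code{"error"}
#'   (default) or \code{"zero"} to replace them by 0.
#' @return list with \code{data} (3D array), \code{affine} (4x4) and
#'   \code{spacing} (mm, length 3), all taken from the header.
#' @export
readVolume <- function(path, nonFinite = c("error", "zero")) {
  nonFinite <- match.arg(nonFinite)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  arr <- array(as.vector(arr), dim(arr))   # drop NIfTI attributes
  if (length(dim(arr)) != 3L)
    stop("expected a 3D image, got ", length(dim(arr)), "D: ", path)
  if (any(!is.finite(arr))) {
    if (nonFinite == "error")
      stop("volume contains non-finite voxels: ", path)
    arr[!is.finite(arr)] <- 0
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  list(data = arr, affine = aff,
       spacing = as.numeric(RNifti::pixdim(img))[1:3])
}

#' Write a 3D volume as NIfTI-1
#'
#' @param data 3D numeric array.
#' @param path output path (.nii or .nii.gz).
#' @param affine 4x4 voxel-to-world matrix (stored as sform and qform).
#' @param spacing voxel size in mm.
#' @param datatype on-disk datatype passed to \code{RNifti::writeNifti}.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(data, path, affine = diag(4), spacing = c(1, 1, 1),
                        datatype = "auto") {
  img <- RNifti::asNifti(unclass(data))
  RNifti::pixdim(img) <- spacing
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write a segmentation mask as integer NIfTI
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "SegmentationMask"))
  validObject(mask)
  writeVolume(maskLabels(mask), path, affine = volAffine(mask),
              spacing = volSpacing(mask), datatype = "int32")
  invisible(path)
}

#' Default BraTS-style modality filename patterns
#'
#' Regular expressions (matched against basenames) identifying each
#' modality file inside a case directory.  The trailing \code{\\.} keeps
#' \code{_t1.} from matching \code{_t1ce.}.
#' @return named character vector of patterns.
#' @export
defaultCasePatterns <- function() {
  c(flair = "_flair\\.", t1 = "_t1\\.", t1ce = "_t1ce\\.",
    t2 = "_t2\\.", seg = "_seg\\.|seg\\.")
}

#' Load a BraTS-layout case directory
#'
#' Assembles the four modality files of one case into a
#' \linkS4class{MultiModalVolume} (fixed channel order Flair, T1, T1ce, T2)
#' and, when a label file is present, a validated
#' \linkS4class{SegmentationMask}.  Channel order is fixed by the filename
#' patterns, never by directory listing order.
#'
#' @param caseDir directory holding one case.
#' @param patterns named regex vector as \code{\link{defaultCasePatterns}};
#'   must name \code{flair}, \code{t1}, \code{t1ce}, \code{t2} and
#'   optionally \code{seg}.
#' @param labelSet permitted mask labels (default BraTS \code{c(1, 2, 4)}).
#' @param regionMap optional explicit ET/TC/WT mapping.
#' @param nonFinite passed to \code{\link{readVolume}}.
#' @return list with elements \code{volume} (MultiModalVolume) and
#'   \code{mask} (SegmentationMask or NULL).
#' @export
loadCase <- function(caseDir, patterns = defaultCasePatterns(),
                     labelSet = c(1L, 2L, 4L), regionMap = NULL,
                     nonFinite = "error") {
  if (!dir.exists(caseDir)) stop("case directory not found: ", caseDir)
  files <- list.files(caseDir, full.names = TRUE)
  pick <- function(key, required = TRUE) {
    hit <- files[grepl(patterns[[key]], basename(files))]
    if (length(hit) == 0L) {
      if (required)
        stop(sprintf("case %s: no file matches %s pattern '%s'",
                     basename(caseDir), key, patterns[[key]]))
      return(NULL)
    }
    if (length(hit) > 1L)
      stop(sprintf("case %s: pattern '%s' matches %d files",
                   basename(caseDir), patterns[[key]], length(hit)))
    hit
  }
  order <- c("flair", "t1", "t1ce", "t2")
  vols <- lapply(order, function(k) readVolume(pick(k), nonFinite))
  shp <- dim(vols[[1L]]$data)
  for (i in 2:4) {
    if (!all(dim(vols[[i]]$data) == shp))
      stop(sprintf("case %s: channel %s shape (%s) differs from flair (%s)",
                   basename(caseDir), order[i],
                   paste(dim(vols[[i]]$data), collapse = "x"),
                   paste(shp, collapse = "x")))
  }
  vol <- MultiModalVolume(lapply(vols, `[[`, "data"), channels = order,
                          spacing = vols[[1L]]$spacing,
                          affine = vols[[1L]]$affine)
  mask <- NULL
  segPath <- if ("seg" %in% names(patterns)) pick("seg", required = FALSE)
  if (!is.null(segPath)) {
    seg <- readVolume(segPath, nonFinite)
    if (!all(dim(seg$data) == shp))
      stop(sprintf("case %s: mask shape differs from modalities",
                   basename(caseDir)))
    mask <- SegmentationMask(round(seg$data), labelSet = labelSet,
                             regionMap = regionMap, spacing = seg$spacing,
                             affine = seg$affine)
  }
  list(volume = vol, mask = mask)
}
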
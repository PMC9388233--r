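# BraTS-style evaluation: overlap and surface metrics per nested tumor
# region (ET, TC, WT) plus a pixel-level binary confusion matrix.

.asBinaryArray <- function(x) {
  if (is(x, "SegmentationMask")) return(maskLabels(x) > 0L)
  if (is.logical(x)) return(x)
  x > 0
}

#' Boolean region volumes for the nested evaluation regions
#'
#' Under the default BraTS mapping ET = \{4\}, TC = \{1, 4\},
#' WT = \{1, 2, 4\}, so WT contains TC contains ET.
#'
#' @param mask a \linkS4class{SegmentationMask}.
#' @return named list of logical arrays \code{ET}, \code{TC}, \code{WT}.
#' @export
regionMasks <- function(mask) {
  stopifnot(is(mask, "SegmentationMask"))
  validObject(mask)
  lab <- maskLabels(mask)
  lapply(regionMap(mask)[c("ET", "TC", "WT")], function(ls)
    array(lab %in% ls, dim(lab)))
}

#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}; two empty regions count as perfect
#' agreement (Dice 1), following BraTS evaluation convention.
#'
#' @param pred,true logical arrays of one shape.
#' @return scalar in \code{[0, 1]}.
#' @export
diceCoefficient <- function(pred, true) {
  if (!all(dim(pred) == dim(true))) stop("shape mismatch")
  a <- sum(pred); b <- sum(true)
  if (a + b == 0L) return(1)
  2 * sum(pred & true) / (a + b)
}

# boundary voxels: region voxels with at least one 6-neighbor outside the
# region (voxels on the array edge count as boundary)
.boundaryVoxels <- function(region) {
  d <- dim(region)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] <- region
  inner <- pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] &
    pad[1:d[1L], 2:(d[2L] + 1L), 2:(d[3L] + 1L)] &
    pad[3:(d[1L] + 2L), 2:(d[2L] + 1L), 2:(d[3L] + 1L)] &
    pad[2:(d[1L] + 1L), 1:d[2L], 2:(d[3L] + 1L)] &
    pad[2:(d[1L] + 1L), 3:(d[2L] + 2L), 2:(d[3L] + 1L)] &
    pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 1:d[3L]] &
    pad[2:(d[1L] + 1L), 2:(d[2L] + 1L), 3:(d[3L] + 2L)]
  which(region & !inner, arr.ind = TRUE)
}

# for each row of A (n x 3, mm), distance to the nearest row of B
.nearestDistances <- function(A, B, chunk = 2048L) {
  n <- nrow(A)
  out <- numeric(n)
  b2 <- rowSums(B^2)
  for (s in seq(1L, n, chunk)) {
    e <- min(n, s + chunk - 1L)
    Ab <- A[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ab^2), b2, `+`) - 2 * Ab %*% t(B)
    out[s:e] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Robust (95th percentile) symmetric surface distance
#'
#' Surface voxels of both regions are extracted (6-connectivity), all
#' nearest-surface distances are computed in mm using the voxel spacing,
#' and the larger of the two directed distance percentiles is returned.
#' With \code{percentile = 100} this is the classical Hausdorff distance.
#'
#' @param pred,true logical arrays of one shape.
#' @param spacing voxel size in mm.
#' @param percentile distance percentile (default 95, the BraTS
#'   convention).
#' @param emptyPenalty value returned (with a warning) when exactly one
#'   region is empty; default: the volume diagonal in mm.  Two empty
#'   regions agree perfectly and return 0.
#' @return scalar distance in mm.
#' @export
hausdorffDistance <- function(pred, true, spacing = c(1, 1, 1),
                              percentile = 95, emptyPenalty = NULL) {
  if (!all(dim(pred) == dim(true))) stop("shape mismatch")
  np <- sum(pred); nt <- sum(true)
  if (np == 0L && nt == 0L) return(0)
  if (np == 0L || nt == 0L) {
    if (is.null(emptyPenalty))
      emptyPenalty <- sqrt(sum((dim(pred) * spacing)^2))
    warning("one region is empty; returning penalty distance ",
            format(emptyPenalty, digits = 4))
    return(emptyPenalty)
  }
  A <- .boundaryVoxels(pred)
  B <- .boundaryVoxels(true)
  Am <- sweep(A, 2L, spacing, `*`)
  Bm <- sweep(B, 2L, spacing, `*`)
  dAB <- .nearestDistances(Am, Bm)
  dBA <- .nearestDistances(Bm, Am)
  max(as.numeric(quantile(dAB, percentile / 100)),
      as.numeric(quantile(dBA, percentile / 100)))
}

#' Voxel sensitivity and specificity of a binary region
#'
#' sens = TP/(TP+FN), spec = TN/(TN+FP); an undefined ratio (empty
#' denominator) returns 0 with a warning.
#'
#' @param pred,true logical arrays of one shape.
#' @return named numeric vector \code{c(sensitivity, specificity)}.
#' @export
sensitivitySpecificity <- function(pred, true) {
  if (!all(dim(pred) == dim(true))) stop("shape mismatch")
  tp <- sum(pred & true); fn <- sum(!pred & true)
  tn <- sum(!pred & !true); fp <- sum(pred & !true)
  sens <- if (tp + fn == 0L) {
    warning("no positive voxels in truth; sensitivity undefined, using 0")
    0
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0L) {
    warning("no negative voxels in truth; specificity undefined, using 0")
    0
  } else tn / (tn + fp)
  c(sensitivity = sens, specificity = spec)
}

#' Pixel-level binary confusion matrix
#'
#' Counts voxels for the binary tumor (any non-zero label) vs non-tumor
#' task and derives accuracy, precision, recall and F1.  The four counts
#' always sum to the total voxel count.
#'
#' @param pred,true \linkS4class{SegmentationMask} objects or arrays
#'   (non-zero / TRUE = tumor) of one shape.
#' @return list of class \code{"pixelConfusion"} with \code{tp},
#'   \code{fp}, \code{fn}, \code{tn}, \code{accuracy}, \code{precision},
#'   \code{recall}, \code{f1}.
#' @export
pixelConfusion <- function(pred, true) {
  p <- .asBinaryArray(pred); g <- .asBinaryArray(true)
  if (!all(dim(p) == dim(g))) stop("shape mismatch")
  tp <- sum(p & g); fp <- sum(p & !g)
  fn <- sum(!p & g); tn <- sum(!p & !g)
  total <- tp + fp + fn + tn
  prec <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / total, precision = prec,
                 recall = rec, f1 = f1), class = "pixelConfusion")
}

#' @export
print.pixelConfusion <- function(x, ...) {
  cat(sprintf("pixel confusion: TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  accuracy %.4f  precision %.4f  recall %.4f  F1 %.4f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Evaluate one predicted mask against ground truth
#'
#' Dice, robust Hausdorff, sensitivity and specificity for each of ET,
#' TC and WT, plus the pixel-level binary confusion.
#'
#' @param predMask,trueMask \linkS4class{SegmentationMask} objects of
#'   one shape (region maps taken from \code{trueMask}).
#' @param spacing voxel spacing in mm (default: the truth's spacing).
#' @return list with \code{regions} (data.frame, one row per region) and
#'   \code{confusion} (\code{pixelConfusion}).
#' @export
evaluateCase <- function(predMask, trueMask,
                         spacing = volSpacing(trueMask)) {
  predRegions <- regionMasks(predMask)
  trueRegions <- regionMasks(trueMask)
  rows <- lapply(c("ET", "TC", "WT"), function(r) {
    p <- predRegions[[r]]; g <- trueRegions[[r]]
    ss <- suppressWarnings(sensitivitySpecificity(p, g))
    data.frame(region = r,
               dice = diceCoefficient(p, g),
               hausdorff = suppressWarnings(
                 hausdorffDistance(p, g, spacing)),
               sensitivity = ss[["sensitivity"]],
               specificity = ss[["specificity"]])
  })
  list(regions = do.call(rbind, rows),
       confusion = pixelConfusion(predMask, trueMask))
}

#' Aggregate per-case region metrics
#'
#' @param caseResults list of \code{\link{evaluateCase}} results.
#' @return data.frame with mean, standard deviation and median of every
#'   metric per region; invariant to case order.
#' @export
aggregateMetrics <- function(caseResults) {
  all <- do.call(rbind, lapply(caseResults, `[[`, "regions"))
  metrics <- c("dice", "hausdorff", "sensitivity", "specificity")
  out <- do.call(rbind, lapply(split(all, all$region), function(d) {
    do.call(rbind, lapply(metrics, function(m)
      data.frame(region = d$region[1L], metric = m,
                 mean = mean(d[[m]]), stddev = sd(d[[m]]),
                 median = median(d[[m]]))))
  }))
  rownames(out) <- NULL
  out
}
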
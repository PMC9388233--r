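# Shared fixtures, all generated in code at test time.

# small, fast phantom configuration used across test files; tumor radii
# scale with the volume so tiny grids still fit the nested ellipsoids
tinyPhantomConfig <- function(shape = c(32L, 32L, 32L), seed = 0L, ...) {
  if (min(shape) >= 24L) {
    phantomConfig(shape = shape, radiusEdema = c(6, 8),
                  radiusCore = c(4, 5), radiusEnhancing = c(2, 3),
                  seed = seed, ...)
  } else {
    phantomConfig(shape = shape, radiusEdema = c(3, 4),
                  radiusCore = c(2, 2.5), radiusEnhancing = c(1, 1.5),
                  seed = seed, ...)
  }
}

# a hand-buildable mask: zeros except explicitly placed labels
placeLabels <- function(shape, coords, labels) {
  m <- array(0L, shape)
  for (i in seq_len(nrow(coords)))
    m[coords[i, 1L], coords[i, 2L], coords[i, 3L]] <- labels[i]
  m
}

# brute-force directed/symmetric percentile surface distance used as the
# oracle for hausdorffDistance (independent all-pairs implementation)
bruteHausdorff <- function(pred, true, spacing = c(1, 1, 1),
                           percentile = 95) {
  boundary <- function(region) {
    idx <- which(region, arr.ind = TRUE)
    d <- dim(region)
    keep <- logical(nrow(idx))
    for (i in seq_len(nrow(idx))) {
      v <- idx[i, ]
      nb <- rbind(v + c(1, 0, 0), v - c(1, 0, 0), v + c(0, 1, 0),
                  v - c(0, 1, 0), v + c(0, 0, 1), v - c(0, 0, 1))
      outside <- FALSE
      for (j in 1:6) {
        w <- nb[j, ]
        if (any(w < 1) || any(w > d) || !region[w[1], w[2], w[3]]) {
          outside <- TRUE
          break
        }
      }
      keep[i] <- outside
    }
    idx[keep, , drop = FALSE]
  }
  A <- sweep(boundary(pred), 2, spacing, `*`)
  B <- sweep(boundary(true), 2, spacing, `*`)
  direct <- function(P, Q) {
    d <- numeric(nrow(P))
    for (i in seq_len(nrow(P)))
      d[i] <- sqrt(min(colSums((t(Q) - P[i, ])^2)))
    as.numeric(quantile(d, percentile / 100))
  }
  max(direct(A, B), direct(B, A))
}
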
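#' 256-bin intensity histogram used for automatic thresholding
#'
#' 8-bit tiles are binned on their native 0..255 values. 16-bit tiles are
#' first min-max rescaled to 0..255 so that the Triangle construction
#' operates on a histogram of fixed size, matching the behaviour of
#' common auto-threshold toolboxes; [thresholdImage()] maps the selected
#' bin back to native intensity.
#'
#' @param img an [SHGImage-class] or numeric matrix.
#' @param bitDepth bit depth if `img` is a bare matrix.
#' @return list with `counts` (length 256, bins 0..255) and `binValue`,
#'   a function mapping a bin index to native intensity.
#' @keywords internal
intensityHistogram <- function(img, bitDepth = NULL) {
  x <- as.vector(asPixels(img))
  bd <- if (is.null(bitDepth)) imgBitDepth(img) else as.integer(bitDepth)
  if (bd == 8L) {
    bins <- as.integer(x)
    binValue <- function(b) b
  } else {
    lo <- min(x); hi <- max(x)
    if (hi == lo) {
      bins <- rep.int(0L, length(x))
      binValue <- function(b) lo
    } else {
      bins <- as.integer(floor((x - lo) / (hi - lo) * 255.999))
      binValue <- function(b) lo + b / 255 * (hi - lo)
    }
  }
  counts <- tabulate(bins + 1L, nbins = 256L)
  list(counts = counts, binValue = binValue)
}

#' Triangle automatic threshold of a histogram
#'
#' Zack's geometric construction: locate the histogram peak; pick the
#' tail side whose farthest non-empty bin lies further from the peak
#' (ties go to the bright side, since SHG collagen is the bright tail);
#' draw the line from the peak point to that tail-end point; return the
#' bin between them at maximum perpendicular distance below the line.
#'
#' @param counts vector of non-negative bin counts (bin 0 first).
#' @return 0-based index of the threshold bin.
#' @examples
#' h <- c(rep(0, 10), 100, 80, 60, 40, 20, 10, 5, 2, 1, rep(0, 5))
#' triangleThreshold(h)
#' @export
triangleThreshold <- function(counts) {
  if (!length(counts)) stop("empty histogram")
  if (any(counts < 0)) stop("histogram counts must be non-negative")
  nz <- which(counts > 0)
  if (length(nz) < 2L)
    stop("degenerate histogram: fewer than 2 non-empty bins")
  peak <- which.max(counts)            # 1-based
  lo <- nz[1L]; hi <- nz[length(nz)]
  # side with the longer tail; tie -> right (bright) side
  right <- (hi - peak) >= (peak - lo)
  tail_end <- if (right) hi else lo
  if (tail_end == peak)
    stop("degenerate histogram: peak coincides with the tail end")
  idx <- if (right) seq(peak, tail_end) else seq(tail_end, peak)
  # perpendicular distance of (b, counts[b]) from the peak--tail line
  x1 <- peak; y1 <- counts[peak]
  x2 <- tail_end; y2 <- counts[tail_end]
  d <- abs((y2 - y1) * idx - (x2 - x1) * counts[idx] + x2 * y1 - x1 * y2) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  inner <- idx != peak & idx != tail_end
  cand <- if (any(inner)) idx[inner] else idx
  dcand <- if (any(inner)) d[inner] else d
  # tie-break toward the peak so mirrored histograms give mirrored levels
  ord <- order(abs(cand - peak))
  as.integer(cand[ord][which.max(dcand[ord])] - 1L)
}

#' Binarize an image at a threshold level
#'
#' Foreground is strictly *above* the level (intensities "surpassing"
#' the threshold).
#'
#' @param img an [SHGImage-class] or numeric matrix.
#' @param level native-intensity threshold.
#' @return logical matrix, `TRUE` = collagen-positive.
#' @export
binarize <- function(img, level) {
  asPixels(img) > level
}

#' Total collagen area ratio of a binary mask
#'
#' @param mask logical matrix.
#' @return fraction of foreground pixels in `[0, 1]`.
#' @export
tcRatio <- function(mask) {
  if (!is.logical(mask) || !length(mask)) stop("mask must be a non-empty logical matrix")
  sum(mask) / length(mask)
}

#' Triangle-threshold an SHG tile
#'
#' Convenience wrapper combining [intensityHistogram()],
#' [triangleThreshold()], [binarize()] and [tcRatio()].
#'
#' @param img an [SHGImage-class] or numeric matrix.
#' @param bitDepth bit depth if `img` is a bare matrix.
#' @return list with `level` (native intensity), `mask` and `tc_ratio`.
#' @export
thresholdImage <- function(img, bitDepth = NULL) {
  h <- intensityHistogram(img, bitDepth)
  bin <- triangleThreshold(h$counts)
  level <- h$binValue(bin)
  mask <- binarize(img, level)
  list(level = level, mask = mask, tc_ratio = tcRatio(mask))
}
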
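#' Gray-level co-occurrence matrix at pixel distance 1
#'
#' Counts co-occurrences of quantized gray levels between each pixel and
#' its neighbour at distance 1 in one of four directions (0, 45, 90,
#' 135 degrees), symmetrized (each pair counted in both orders) and
#' normalized to sum 1.
#'
#' Quantization: when `levels` equals the full native range (256 for an
#' 8-bit tile) pixel values index the matrix directly; otherwise the
#' intensity range is min-max rescaled to `levels` bins (this is also how
#' 16-bit tiles are reduced to the 256-level matrix the texture features
#' are defined on).
#'
#' @param img an [SHGImage-class] or numeric matrix.
#' @param direction one of `0`, `45`, `90`, `135` (degrees).
#' @param levels number of gray levels L; the matrix is L x L.
#' @param bitDepth bit depth if `img` is a bare matrix.
#' @return L x L numeric matrix with entries summing to 1.
#' @examples
#' chk <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
#' computeGLCM(chk, direction = 0, levels = 2)
#' @export
computeGLCM <- function(img, direction = 0, levels = 256L, bitDepth = NULL) {
  p <- asPixels(img)
  L <- as.integer(levels)
  bd <- if (is.null(bitDepth)) imgBitDepth(img) else as.integer(bitDepth)
  q <- quantizeLevels(p, L, bd)
  off <- glcmOffset(direction)
  nr <- nrow(q); nc <- ncol(q)
  dr <- off[1L]; dc <- off[2L]
  rs <- max(1L, 1L - dr); re <- min(nr, nr - dr)
  cs <- max(1L, 1L - dc); ce <- min(nc, nc - dc)
  if (rs > re || cs > ce)
    stop("image too small for offset in direction ", direction)
  r1 <- rs:re; c1 <- cs:ce
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- tabulate(as.vector(a) * L + as.vector(b) + 1L, nbins = L * L)
  m <- matrix(counts, L, L, byrow = TRUE)  # row i = first level
  m <- m + t(m)                            # symmetrize
  m / sum(m)
}

quantizeLevels <- function(p, L, bitDepth) {
  if (L == 2L^bitDepth) return(matrix(as.integer(p), nrow(p), ncol(p)))
  lo <- min(p); hi <- max(p)
  if (hi == lo) return(matrix(0L, nrow(p), ncol(p)))
  q <- floor((p - lo) / (hi - lo) * L)
  q[q >= L] <- L - 1L
  matrix(as.integer(q), nrow(p), ncol(p))
}

glcmOffset <- function(direction) {
  # (row, col) offset of the neighbour; rows increase downward
  switch(as.character(direction),
    "0"   = c(0L, 1L),
    "45"  = c(-1L, 1L),
    "90"  = c(-1L, 0L),
    "135" = c(-1L, -1L),
    stop("direction must be one of 0, 45, 90, 135")
  )
}

#' Texture features of a normalized GLCM
#'
#' With \eqn{p(i,j)} the normalized co-occurrence probabilities:
#' contrast \eqn{\sum p(i,j)(i-j)^2}; homogeneity (inverse difference
#' moment) \eqn{\sum p(i,j)/(1+(i-j)^2)}; energy (angular second moment)
#' \eqn{\sum p(i,j)^2}; entropy \eqn{-\sum p(i,j)\log_2 p(i,j)} with
#' \eqn{0\log 0 = 0}; correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j)p(i,j)/(\sigma_i\sigma_j)} from the
#' marginal means and standard deviations. For a constant image the
#' marginal variance is zero and correlation is returned as `NA` with a
#' warning.
#'
#' @param glcm normalized GLCM from [computeGLCM()].
#' @return named list: `contrast`, `homogeneity`, `energy`, `entropy`,
#'   `correlation`.
#' @export
glcmFeatures <- function(glcm) {
  if (abs(sum(glcm) - 1) > 1e-8) stop("GLCM must be normalized to sum 1")
  L <- nrow(glcm)
  i <- matrix(0:(L - 1L), L, L)
  j <- t(i)
  d2 <- (i - j)^2
  nz <- glcm > 0
  contrast <- sum(glcm * d2)
  homogeneity <- sum(glcm / (1 + d2))
  energy <- sum(glcm^2)
  entropy <- -sum(glcm[nz] * log2(glcm[nz]))
  pi_ <- rowSums(glcm)
  mu_i <- sum((0:(L - 1L)) * pi_)
  var_i <- sum(((0:(L - 1L)) - mu_i)^2 * pi_)
  pj_ <- colSums(glcm)
  mu_j <- sum((0:(L - 1L)) * pj_)
  var_j <- sum(((0:(L - 1L)) - mu_j)^2 * pj_)
  if (var_i * var_j == 0) {
    warning("constant gray level: GLCM correlation is undefined")
    correlation <- NA_real_
  } else {
    correlation <- sum((i - mu_i) * (j - mu_j) * glcm) /
      sqrt(var_i * var_j)
  }
  list(contrast = contrast, homogeneity = homogeneity, energy = energy,
       entropy = entropy, correlation = correlation)
}

#' Direction-averaged GLCM texture features
#'
#' Arithmetic mean of each of the five features over the four distance-1
#' directions (horizontal, vertical, both diagonals). An undefined
#' correlation in any direction propagates `NA`.
#'
#' @inheritParams computeGLCM
#' @return named list as in [glcmFeatures()].
#' @export
averagedGLCMFeatures <- function(img, levels = 256L, bitDepth = NULL) {
  feats <- lapply(c(0, 45, 90, 135), function(d)
    glcmFeatures(computeGLCM(img, direction = d, levels = levels,
                             bitDepth = bitDepth)))
  out <- lapply(names(feats[[1L]]), function(nm) {
    v <- vapply(feats, function(f) f[[nm]], numeric(1))
    if (anyNA(v)) NA_real_ else mean(v)
  })
  names(out) <- names(feats[[1L]])
  out
}
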
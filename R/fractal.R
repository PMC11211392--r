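#' Box counts of a binary mask over a size ladder
#'
#' For each box size `s` the mask is tiled by an `s x s` grid anchored
#' at the image origin (no offset averaging by default, matching the
#' basic box-count plugins) and boxes containing at least one foreground
#' pixel are counted.
#'
#' @param mask logical matrix with non-empty foreground.
#' @param sizes integer box sizes, each at least 2 and at most the
#'   smaller image dimension.
#' @return integer vector of occupied-box counts, one per size.
#' @export
boxCount <- function(mask, sizes) {
  if (!is.logical(mask)) stop("mask must be logical")
  if (!any(mask)) stop("no foreground in mask")
  sizes <- as.integer(sizes)
  if (any(sizes < 2L) || any(sizes > min(dim(mask))))
    stop("box sizes must lie in [2, min(image dimension)]")
  idx <- which(mask, arr.ind = TRUE)
  vapply(sizes, function(s) {
    br <- (idx[, 1L] - 1L) %/% s
    bc <- (idx[, 2L] - 1L) %/% s
    ncolBoxes <- (ncol(mask) + s - 1L) %/% s
    length(unique(br * ncolBoxes + bc))
  }, integer(1))
}

#' Default power-of-two box-size ladder
#'
#' Powers of 2 from 2 up to `min(dim)/4`, giving exact tilings and a
#' reproducible log-log fit.
#'
#' @param mask logical matrix.
#' @return integer vector of box sizes.
#' @export
defaultBoxSizes <- function(mask) {
  top <- min(dim(mask)) / 4
  s <- 2L^(1:30)
  s[s <= top]
}

#' Box-counting fractal dimension of a binary mask
#'
#' `D` is the slope of the least-squares fit of `log(count)` against
#' `log(1/size)` over the size ladder. For a 2-D mask `D` lies in
#' `[0, 2]`: a filled region gives 2, a straight line 1.
#'
#' @param mask logical matrix with non-empty foreground.
#' @param sizes box-size ladder; defaults to [defaultBoxSizes()].
#' @return list with `D`, `box_sizes`, `counts` and `r2` (goodness of
#'   the log-log fit).
#' @export
fractalDimension <- function(mask, sizes = NULL) {
  if (is.null(sizes)) sizes <- defaultBoxSizes(mask)
  if (length(sizes) < 3L)
    stop("need at least 3 usable box sizes for the log-log fit")
  counts <- boxCount(mask, sizes)
  lx <- log(1 / sizes)
  ly <- log(counts)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  D <- unname(fit$coefficients[2L])
  ssr <- sum(fit$residuals^2)
  sst <- sum((ly - mean(ly))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 1
  list(D = D, box_sizes = sizes, counts = counts, r2 = r2)
}
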
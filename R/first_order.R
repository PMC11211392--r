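#' First-order histogram statistics of an SHG tile
#'
#' Computes the four parameters describing the pixel-intensity
#' distribution of a tile: mean, standard deviation, skewness and
#' kurtosis. Moments are population moments (no small-sample
#' correction): with central moments \eqn{m_k}, skewness is
#' \eqn{g_1 = m_3/m_2^{3/2}} and kurtosis is reported in *excess* form
#' \eqn{g_2 = m_4/m_2^2 - 3}, so a Gaussian intensity distribution has
#' skewness 0 and kurtosis 0. Statistics are computed on all pixels of
#' the tile, with no background exclusion.
#'
#' For a constant tile (`sd == 0`) skewness and kurtosis are undefined
#' and returned as `NA` with a warning; downstream group comparison
#' treats such rows as missing.
#'
#' @param img an [SHGImage-class] or numeric matrix.
#' @return named list with elements `mean`, `sd`, `skewness`, `kurtosis`.
#' @examples
#' firstOrderStats(matrix(c(0, 1), 8, 8))  # two-point symmetric
#' @export
firstOrderStats <- function(img) {
  x <- as.vector(asPixels(img))
  if (!length(x)) stop("empty image")
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  if (m2 == 0) {
    warning("constant image: skewness and kurtosis are undefined")
    return(list(mean = mu, sd = 0, skewness = NA_real_,
                kurtosis = NA_real_))
  }
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  list(mean = mu,
       sd = sqrt(m2),
       skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3)
}
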
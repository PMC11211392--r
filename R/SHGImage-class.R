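#' SHGImage: a single-channel SHG intensity tile
#'
#' The unit of analysis for the whole pipeline: one grayscale second
#' harmonic generation (SHG) image tile. Pixels are stored as a numeric
#' matrix of non-negative integer intensities at native bit depth
#' (8- or 16-bit); all twelve collagen parameters are computed from this
#' object.
#'
#' @slot pixels numeric matrix of intensities, rows = image rows.
#' @slot bitDepth integer, 8 or 16; intensities must lie in
#'   \eqn{[0, 2^{bitDepth}-1]}.
#' @slot sourceId free-text provenance label (usually the file stem).
#'
#' @seealso [readSHGImage()], [measureImage()]
#' @examples
#' img <- SHGImage(matrix(0:63, 8, 8), bitDepth = 8L)
#' img
#' firstOrderStats(img)
#' @name SHGImage-class
#' @aliases SHGImage-class pixels,SHGImage-method bitDepth,SHGImage-method
#'   sourceId,SHGImage-method show,SHGImage-method
#' @export
setClass("SHGImage",
  representation(
    pixels = "matrix",
    bitDepth = "integer",
    sourceId = "character"
  ),
  prototype(bitDepth = 8L, sourceId = "unknown")
)

setValidity("SHGImage", function(object) {
  msg <- character()
  p <- object@pixels
  if (!is.numeric(p))
    msg <- c(msg, "pixels must be a numeric matrix")
  if (length(dim(p)) != 2L)
    msg <- c(msg, "pixels must be a single-channel 2-D matrix")
  if (nrow(p) < 8L || ncol(p) < 8L)
    msg <- c(msg, "image must be at least 8x8 pixels")
  if (!(object@bitDepth %in% c(8L, 16L)))
    msg <- c(msg, "bitDepth must be 8 or 16")
  if (is.numeric(p) && length(p)) {
    if (anyNA(p))
      msg <- c(msg, "pixels must not contain NA")
    else {
      if (min(p) < 0) msg <- c(msg, "intensities must be non-negative")
      if (max(p) > 2^object@bitDepth - 1)
        msg <- c(msg, sprintf("intensities exceed 2^%d - 1", object@bitDepth))
    }
  }
  if (length(object@sourceId) != 1L)
    msg <- c(msg, "sourceId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct an SHGImage
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param bitDepth 8 or 16.
#' @param sourceId provenance label.
#' @return an [SHGImage-class] object.
#' @export
SHGImage <- function(pixels, bitDepth = 8L, sourceId = "unknown") {
  new("SHGImage", pixels = pixels, bitDepth = as.integer(bitDepth),
      sourceId = as.character(sourceId))
}

#' @export
setMethod("pixels", "SHGImage", function(x) x@pixels)

#' @export
setMethod("bitDepth", "SHGImage", function(x) x@bitDepth)

#' @export
setMethod("sourceId", "SHGImage", function(x) x@sourceId)

#' @export
setMethod("dim", "SHGImage", function(x) dim(x@pixels))

setMethod("show", "SHGImage", function(object) {
  p <- object@pixels
  cat(sprintf("SHGImage '%s': %d x %d, %d-bit\n",
              object@sourceId, nrow(p), ncol(p), object@bitDepth))
  cat(sprintf("  intensity range [%g, %g], mean %.4g\n",
              min(p), max(p), mean(p)))
  invisible(NULL)
})

# Accept either an SHGImage or a bare numeric matrix in computational
# routines; the class enforces tile invariants for images read from disk,
# while small literal matrices remain convenient in examples and tests.
asPixels <- function(x) {
  if (methods::is(x, "SHGImage")) return(x@pixels)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected an SHGImage or a numeric matrix")
}

imgBitDepth <- function(x, default = 8L) {
  if (methods::is(x, "SHGImage")) x@bitDepth else as.integer(default)
}
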
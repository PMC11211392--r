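#' Canonical parameter names
#'
#' The twelve per-image collagen parameters, in fixed column order:
#' four first-order histogram statistics, the total collagen area ratio,
#' five direction-averaged GLCM texture features, the FFT orientation
#' index and the box-counting fractal dimension.
#'
#' @return character vector of length 12.
#' @export
parameterNames <- function() {
  c("mean", "sd", "skewness", "kurtosis", "tc_ratio",
    "contrast", "homogeneity", "energy", "entropy", "correlation",
    "orientation_index", "fractal_dimension")
}

#' Read a grayscale image tile
#'
#' Reads an 8- or 16-bit TIFF or PNG into an [SHGImage-class] at native
#' intensity scale. RGB input whose channels are identical is collapsed
#' to a single channel; RGB with differing channels is rejected so the
#' caller can select a channel explicitly.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @return an [SHGImage-class]; `sourceId` is the file stem.
#' @export
readSHGImage <- function(path) {
  if (!file.exists(path))
    stop("cannot read image: file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  res <- switch(ext,
    "tif" = , "tiff" = readTiffNative(path),
    "png" = readPngNative(path),
    stop("unsupported image format '", ext, "' for: ", path)
  )
  arr <- res$pixels
  if (length(dim(arr)) == 3L) {
    nch <- dim(arr)[3L]
    chans <- lapply(seq_len(nch), function(k) arr[, , k])
    if (nch == 4L) chans <- chans[1:3]  # drop alpha
    same <- all(vapply(chans[-1], function(ch)
      isTRUE(all.equal(ch, chans[[1L]], tolerance = 0)), logical(1)))
    if (!same)
      stop("RGB image with differing channels: ", path,
           "; extract the desired channel before analysis")
    arr <- chans[[1L]]
  }
  SHGImage(arr, bitDepth = res$bitDepth,
           sourceId = tools::file_path_sans_ext(basename(path)))
}

readTiffNative <- function(path) {
  res <- tryCatch(tiff::readTIFF(path, as.is = TRUE, info = TRUE),
                  error = function(e)
                    stop("cannot read image '", path, "': ",
                         conditionMessage(e)))
  bits <- attr(res, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  px <- unclass(res) * 1.0
  attributes(px) <- list(dim = dim(px))
  list(pixels = px, bitDepth = as.integer(bits))
}

readPngNative <- function(path) {
  raw01 <- tryCatch(png::readPNG(path),
                    error = function(e)
                      stop("cannot read image '", path, "': ",
                           conditionMessage(e)))
  # bit depth from the IHDR chunk (byte 25 of the file)
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 25L)
  bits <- as.integer(hdr[25L])
  if (!(bits %in% c(8L, 16L)))
    stop("unsupported PNG bit depth ", bits, " in: ", path)
  list(pixels = round(unclass(raw01) * (2^bits - 1)), bitDepth = bits)
}

#' Write an SHGImage to disk
#'
#' Pixel-exact inverse of [readSHGImage()] for both bit depths.
#'
#' @param img an [SHGImage-class].
#' @param path destination `.tif`/`.tiff` or `.png` path.
#' @return `path`, invisibly.
#' @export
writeSHGImage <- function(img, path) {
  stopifnot(methods::is(img, "SHGImage"))
  scaled <- img@pixels / (2^img@bitDepth - 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "tif" = , "tiff" =
      tiff::writeTIFF(scaled, path, bits.per.sample = img@bitDepth),
    "png" = png::writePNG(scaled, path),
    stop("unsupported image format '", ext, "'")
  )
  invisible(path)
}

#' Write a per-image parameter table
#'
#' One row per image with the canonical column order
#' `source_id` + [parameterNames()]. Values survive a write/read
#' round trip to at least 12 significant digits; the decimal separator is
#' always `.` regardless of locale.
#'
#' @param tab data.frame with columns `source_id` and the 12 parameters.
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
writeParameterTable <- function(tab, path) {
  if (!is.data.frame(tab) || nrow(tab) == 0L)
    stop("parameter table must be a non-empty data.frame")
  cols <- c("source_id", parameterNames())
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("parameter table lacks columns: ", paste(missing, collapse = ", "))
  if (!dir.exists(dirname(path)))
    stop("output directory does not exist: ", dirname(path))
  out <- tab[, cols]
  for (nm in parameterNames())
    out[[nm]] <- vapply(out[[nm]], function(v)
      if (is.na(v)) "NA" else sprintf("%.15g", v), character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a parameter table written by [writeParameterTable()]
#'
#' @param path CSV path.
#' @return data.frame with `source_id` and the 12 numeric parameter columns.
#' @export
readParameterTable <- function(path) {
  if (!file.exists(path)) stop("no such parameter table: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("source_id", parameterNames())
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("malformed parameter table, missing column(s): ",
         paste(missing, collapse = ", "))
  for (nm in parameterNames()) tab[[nm]] <- as.numeric(tab[[nm]])
  tab[, cols]
}
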
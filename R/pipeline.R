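#' Analysis configuration
#'
#' Collects every convention of the pipeline in one auditable place so
#' that ambiguous choices can be swapped: the automatic threshold for
#' the collagen mask, the GLCM gray-level count, the power-spectrum
#' binarization method, the box-size ladder and the t-test flavour.
#'
#' @param thresholdMethod collagen mask threshold; only `"triangle"` is
#'   implemented (the method the pipeline is built around).
#' @param glcmLevels gray levels for the co-occurrence matrix.
#' @param spectrumMethod `"triangle"` (default) or `"otsu"` for the log-power
#'   spectrum binarization.
#' @param boxSizes explicit box-size ladder or `NULL` for the default
#'   power-of-two ladder.
#' @param welch use Welch's t-test instead of pooled Student's t.
#' @param alpha significance threshold.
#' @param adjust multiple-testing adjustment (`"none"` by default,
#'   matching a per-parameter read of the twelve tests).
#' @return named list of settings.
#' @export
shgConfig <- function(thresholdMethod = "triangle", glcmLevels = 256L,
                      spectrumMethod = "triangle", boxSizes = NULL,
                      welch = FALSE, alpha = 0.05, adjust = "none") {
  stopifnot(thresholdMethod == "triangle",
            spectrumMethod %in% c("otsu", "triangle"))
  list(thresholdMethod = thresholdMethod,
       glcmLevels = as.integer(glcmLevels),
       spectrumMethod = spectrumMethod, boxSizes = boxSizes,
       welch = isTRUE(welch), alpha = alpha, adjust = adjust)
}

#' Measure the twelve collagen parameters of one tile
#'
#' Runs the full per-image chain: first-order histogram statistics,
#' Triangle threshold and TC-ratio, direction-averaged GLCM features,
#' FFT orientation index, and the box-counting fractal dimension of the
#' Triangle mask. Degenerate tiles (e.g. constant intensity) yield `NA`
#' sentinels for the affected parameters with a warning, never an
#' error, so batch runs keep going.
#'
#' @param img an [SHGImage-class] or numeric matrix.
#' @param config settings from [shgConfig()].
#' @return named numeric vector of length 12 ([parameterNames()]).
#' @export
measureImage <- function(img, config = shgConfig()) {
  out <- stats::setNames(rep(NA_real_, 12L), parameterNames())
  fo <- firstOrderStats(img)
  out["mean"] <- fo$mean; out["sd"] <- fo$sd
  out["skewness"] <- fo$skewness; out["kurtosis"] <- fo$kurtosis

  thr <- tryCatch(thresholdImage(img), error = function(e) {
    warning("thresholding failed (", conditionMessage(e),
            "); tc_ratio and fractal_dimension are undefined")
    NULL
  })
  if (!is.null(thr)) out["tc_ratio"] <- thr$tc_ratio

  tex <- averagedGLCMFeatures(img, levels = config$glcmLevels)
  out["contrast"] <- tex$contrast; out["homogeneity"] <- tex$homogeneity
  out["energy"] <- tex$energy; out["entropy"] <- tex$entropy
  out["correlation"] <- tex$correlation

  ori <- tryCatch(orientationIndex(img, method = config$spectrumMethod),
                  error = function(e) {
                    warning("orientation index failed (",
                            conditionMessage(e), ")")
                    NULL
                  })
  if (!is.null(ori)) out["orientation_index"] <- ori$N

  if (!is.null(thr) && any(thr$mask)) {
    fr <- tryCatch(fractalDimension(thr$mask, sizes = config$boxSizes),
                   error = function(e) {
                     warning("fractal dimension failed (",
                             conditionMessage(e), ")")
                     NULL
                   })
    if (!is.null(fr)) out["fractal_dimension"] <- fr$D
  }
  out
}

#' Measure a set of tiles into a parameter table
#'
#' @param images list of [SHGImage-class] objects, or a character vector
#'   of image paths read via [readSHGImage()].
#' @param config settings from [shgConfig()].
#' @param verbose log one line per tile to stderr.
#' @return data.frame with `source_id` plus the 12 parameter columns,
#'   one row per tile (unreadable files are logged and skipped).
#' @export
measureImages <- function(images, config = shgConfig(), verbose = FALSE) {
  if (is.character(images)) {
    imgs <- list(); ok <- 0L
    for (p in images) {
      im <- tryCatch(readSHGImage(p), error = function(e) {
        message("skipping unreadable image: ", conditionMessage(e))
        NULL
      })
      if (!is.null(im)) { imgs[[length(imgs) + 1L]] <- im; ok <- ok + 1L }
    }
    if (ok == 0L) stop("no readable images among ", length(images), " input(s)")
    images <- imgs
  }
  rows <- lapply(images, function(im) {
    t0 <- proc.time()[["elapsed"]]
    v <- measureImage(im, config)
    if (verbose)
      message(sprintf("measured %s in %.2fs%s", sourceId(im),
                      proc.time()[["elapsed"]] - t0,
                      if (anyNA(v)) " [degenerate fields]" else ""))
    cbind(data.frame(source_id = sourceId(im), stringsAsFactors = FALSE),
          as.data.frame(as.list(v)))
  })
  do.call(rbind, rows)
}

#' Compare two measured groups end to end
#'
#' @param tableA,tableB parameter tables (data.frames or CSV paths).
#' @param config settings from [shgConfig()].
#' @return the comparison data.frame of [compareParameterTables()];
#'   attribute `n_significant` counts parameters with `p < alpha`.
#' @export
compareGroups <- function(tableA, tableB, config = shgConfig()) {
  if (is.character(tableA)) tableA <- readParameterTable(tableA)
  if (is.character(tableB)) tableB <- readParameterTable(tableB)
  compareParameterTables(tableA, tableB, alpha = config$alpha,
                         welch = config$welch, adjust = config$adjust)
}

#' Write a comparison table with its summary line
#'
#' @param comparison result of [compareGroups()].
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeComparisonTable <- function(comparison, path) {
  utils::write.csv(comparison, path, row.names = FALSE, quote = TRUE)
  nSig <- attr(comparison, "n_significant")
  nTested <- sum(!is.na(comparison$p_value))
  message(sprintf("%d of %d parameters significant", nSig, nTested))
  invisible(path)
}
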
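#' FiberFieldConfig: generative parameters for a synthetic SHG tile
#'
#' Describes one class of synthetic collagen-fiber field. Fibers are
#' rendered as jittered random-walk polylines: each fiber draws its
#' overall heading from a von Mises distribution with mean
#' `orientationMu` (degrees) and concentration `orientationKappa`
#' (`kappa = 0` is uniformly random orientation), then wanders by
#' Gaussian per-step heading jitter (`curvatureJitter`, degrees/step).
#' Fiber lengths are log-normal with mean `lengthMean` and standard
#' deviation `lengthSd` (pixels). The stamped field is blurred by a
#' Gaussian point-spread function (`psfSigma`, pixels), offset by
#' `backgroundLevel`, degraded by additive Gaussian noise (`noiseSd`)
#' and clipped to the bit depth.
#'
#' @slot imageSize integer, tile side in pixels.
#' @slot nFibers integer fiber count.
#' @slot lengthMean,lengthSd log-normal fiber length (pixels).
#' @slot width fiber width (pixels).
#' @slot orientationMu mean fiber direction (degrees).
#' @slot orientationKappa von Mises concentration (0 = random).
#' @slot fiberIntensity stamped fiber intensity (intensity units).
#' @slot curvatureJitter per-step heading jitter (degrees).
#' @slot psfSigma Gaussian blur sigma (pixels).
#' @slot backgroundLevel,noiseSd background offset and noise sigma.
#' @slot bitDepth 8 or 16.
#' @name FiberFieldConfig-class
#' @aliases FiberFieldConfig-class show,FiberFieldConfig-method
#' @seealso [fiberFieldConfig()], [classPreset()], [generateFiberImage()]
#' @export
setClass("FiberFieldConfig",
  representation(
    imageSize = "integer", nFibers = "integer",
    lengthMean = "numeric", lengthSd = "numeric", width = "numeric",
    orientationMu = "numeric", orientationKappa = "numeric",
    fiberIntensity = "numeric", curvatureJitter = "numeric",
    psfSigma = "numeric", backgroundLevel = "numeric",
    noiseSd = "numeric", bitDepth = "integer"
  )
)

setValidity("FiberFieldConfig", function(object) {
  msg <- character()
  if (object@imageSize < 16L) msg <- c(msg, "imageSize must be >= 16")
  if (object@nFibers < 0L) msg <- c(msg, "nFibers must be >= 0")
  if (object@orientationKappa < 0) msg <- c(msg, "orientationKappa must be >= 0")
  if (object@lengthMean <= 0 || object@lengthSd < 0)
    msg <- c(msg, "fiber lengths must be positive")
  if (object@width < 1) msg <- c(msg, "width must be >= 1 pixel")
  if (!(object@bitDepth %in% c(8L, 16L))) msg <- c(msg, "bitDepth must be 8 or 16")
  maxI <- 2^object@bitDepth - 1
  if (object@fiberIntensity < 0 || object@fiberIntensity > maxI ||
      object@backgroundLevel < 0 || object@backgroundLevel > maxI)
    msg <- c(msg, "intensities must lie within the bit depth")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FiberFieldConfig", function(object) {
  cat(sprintf(paste0(
    "FiberFieldConfig: %d fibers on %dx%d (%d-bit)\n",
    "  length ~ logN(mean %.0f, sd %.0f) px, width %.1f px\n",
    "  orientation vonMises(mu %.0f deg, kappa %.2f), jitter %.1f deg/step\n",
    "  intensity %.0f on background %.0f, psf sigma %.2f, noise sd %.1f\n"),
    object@nFibers, object@imageSize, object@imageSize, object@bitDepth,
    object@lengthMean, object@lengthSd, object@width,
    object@orientationMu, object@orientationKappa, object@curvatureJitter,
    object@fiberIntensity, object@backgroundLevel, object@psfSigma,
    object@noiseSd))
  invisible(NULL)
})

#' Construct a FiberFieldConfig
#'
#' @param imageSize tile side in pixels.
#' @param nFibers fiber count.
#' @param lengthMean,lengthSd log-normal fiber length mean/sd (pixels).
#' @param width fiber width (pixels).
#' @param orientationMu mean direction (degrees).
#' @param orientationKappa von Mises concentration (0 = random).
#' @param fiberIntensity stamped intensity.
#' @param curvatureJitter per-step heading jitter (degrees).
#' @param psfSigma Gaussian PSF sigma (pixels).
#' @param backgroundLevel,noiseSd background offset / noise sigma.
#' @param bitDepth 8 or 16.
#' @return a [FiberFieldConfig-class].
#' @export
fiberFieldConfig <- function(imageSize = 512L, nFibers = 80L,
                             lengthMean = 120, lengthSd = 40, width = 2.5,
                             orientationMu = 0, orientationKappa = 1,
                             fiberIntensity = 160, curvatureJitter = 5,
                             psfSigma = 1.2, backgroundLevel = 20,
                             noiseSd = 6, bitDepth = 8L) {
  new("FiberFieldConfig",
      imageSize = as.integer(imageSize), nFibers = as.integer(nFibers),
      lengthMean = lengthMean, lengthSd = lengthSd, width = width,
      orientationMu = orientationMu, orientationKappa = orientationKappa,
      fiberIntensity = fiberIntensity, curvatureJitter = curvatureJitter,
      psfSigma = psfSigma, backgroundLevel = backgroundLevel,
      noiseSd = noiseSd, bitDepth = as.integer(bitDepth))
}

#' Class presets for the two stromal phenotypes
#'
#' `"invasion"` emulates desmoplastic stroma at a tumor invasion front:
#' dense, long, relatively aligned collagen fascicles. `"pseudoinvasion"`
#' emulates the fibro-muscular reaction around misplaced glands: sparse,
#' short fibers with no consistent alignment. The invasion preset has
#' higher fiber count, mean length and orientation concentration by
#' construction. All numbers are package conventions chosen to give
#' visually plausible 8-bit SHG-like tiles.
#'
#' @param name `"invasion"` or `"pseudoinvasion"`.
#' @param imageSize tile side in pixels (fiber count and length scale
#'   with the tile linearly so smaller tiles remain comparable).
#' @return a [FiberFieldConfig-class].
#' @export
classPreset <- function(name = c("invasion", "pseudoinvasion"),
                        imageSize = 512L) {
  name <- match.arg(name)
  scale <- imageSize / 512
  if (name == "invasion") {
    fiberFieldConfig(imageSize = imageSize,
                     nFibers = round(120 * scale^2),
                     lengthMean = 200 * scale, lengthSd = 60 * scale,
                     width = 3, orientationMu = 0, orientationKappa = 6,
                     fiberIntensity = 170, curvatureJitter = 4,
                     psfSigma = 1.2, backgroundLevel = 20, noiseSd = 6)
  } else {
    fiberFieldConfig(imageSize = imageSize,
                     nFibers = round(45 * scale^2),
                     lengthMean = 60 * scale, lengthSd = 20 * scale,
                     width = 2, orientationMu = 0, orientationKappa = 0.5,
                     fiberIntensity = 140, curvatureJitter = 8,
                     psfSigma = 1.2, backgroundLevel = 20, noiseSd = 6)
  }
}

# von Mises sampler, Best & Fisher (1979) rejection method.
# Returns angles in radians in (-pi, pi] around mu.
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2L] > 0 || log(c_ / u[3L]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3L] - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Render one synthetic collagen-fiber tile
#'
#' Deterministic given `(config, seed)`: the same pair always yields a
#' pixel-identical image. See [FiberFieldConfig-class] for the
#' generative model.
#'
#' @param config a [FiberFieldConfig-class].
#' @param seed integer RNG seed.
#' @param sourceId provenance label for the generated tile.
#' @return an [SHGImage-class].
#' @export
generateFiberImage <- function(config, seed = 1L,
                               sourceId = sprintf("synthetic_%d", seed)) {
  stopifnot(methods::is(config, "FiberFieldConfig"))
  methods::validObject(config)
  withSeed(seed, {
    n <- config@imageSize
    canvas <- matrix(0, n, n)
    maxI <- 2^config@bitDepth - 1
    if (config@nFibers > 0L) {
      sdlog <- sqrt(log(1 + (config@lengthSd / config@lengthMean)^2))
      meanlog <- log(config@lengthMean) - sdlog^2 / 2
      lens <- pmax(4, stats::rlnorm(config@nFibers, meanlog, sdlog))
      heads0 <- rvonmises(config@nFibers, config@orientationMu * pi / 180,
                          config@orientationKappa)
      halfw <- config@width / 2
      dsk <- diskOffsets(halfw)
      step <- 0.5
      for (k in seq_len(config@nFibers)) {
        nstep <- max(2L, ceiling(lens[k] / step))
        jit <- stats::rnorm(nstep, 0, config@curvatureJitter * pi / 180 * step)
        heading <- heads0[k] + cumsum(jit)
        r0 <- stats::runif(1, 1, n); c0 <- stats::runif(1, 1, n)
        # rows grow downward: negate the sine so a positive heading is
        # counter-clockwise from the x axis, matching ellipse angles
        rr <- r0 - cumsum(step * sin(heading))
        cc <- c0 + cumsum(step * cos(heading))
        pr <- round(outer(rr, dsk[, 1L], `+`))
        pc <- round(outer(cc, dsk[, 2L], `+`))
        keep <- pr >= 1 & pr <= n & pc >= 1 & pc <= n
        if (any(keep))
          canvas[cbind(pr[keep], pc[keep])] <- config@fiberIntensity
      }
    }
    if (config@psfSigma > 0)
      canvas <- EBImage::gblur(canvas, sigma = config@psfSigma)
    canvas <- canvas + config@backgroundLevel +
      matrix(stats::rnorm(n * n, 0, config@noiseSd), n, n)
    canvas <- round(pmin(pmax(canvas, 0), maxI))
    SHGImage(canvas, bitDepth = config@bitDepth, sourceId = sourceId)
  })
}

diskOffsets <- function(halfw) {
  r <- ceiling(halfw)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= max(halfw, 0.5)^2 + 1e-9
  as.matrix(g[keep, , drop = FALSE])
}

#' Generate a cohort of synthetic tiles
#'
#' Draws `n` tiles from a class preset with per-image seeds derived
#' deterministically from `masterSeed` and per-image jitter of the
#' generative parameters to create within-class variance: fiber count
#' and mean length vary by +/-15%, orientation concentration by +/-20%,
#' fiber intensity by +/-10%, and each tile gets its own mean direction
#' (uniform over 180 degrees, emulating arbitrary tumor-axis
#' orientation across fields).
#'
#' @param preset a [FiberFieldConfig-class] (e.g. from [classPreset()]).
#' @param n number of tiles.
#' @param masterSeed integer seed governing the whole cohort.
#' @param idPrefix prefix for per-tile `sourceId`s.
#' @return list of `n` [SHGImage-class] tiles; attribute `"truth"` holds
#'   a data.frame of the planted per-image parameters.
#' @export
generateCohort <- function(preset, n, masterSeed = 1L, idPrefix = "tile") {
  stopifnot(methods::is(preset, "FiberFieldConfig"), n >= 1)
  plan <- withSeed(masterSeed, {
    data.frame(
      seed = sample.int(.Machine$integer.max %/% 2L, n),
      nFibers = round(preset@nFibers * stats::runif(n, 0.85, 1.15)),
      lengthMean = preset@lengthMean * stats::runif(n, 0.85, 1.15),
      kappa = preset@orientationKappa * stats::runif(n, 0.8, 1.2),
      intensity = preset@fiberIntensity * stats::runif(n, 0.9, 1.1),
      mu = stats::runif(n, 0, 180)
    )
  })
  plan$source_id <- sprintf("%s_%03d", idPrefix, seq_len(n))
  imgs <- lapply(seq_len(n), function(i) {
    cfg <- preset
    cfg@nFibers <- as.integer(plan$nFibers[i])
    cfg@lengthMean <- plan$lengthMean[i]
    cfg@orientationKappa <- plan$kappa[i]
    cfg@fiberIntensity <- min(plan$intensity[i], 2^preset@bitDepth - 1)
    cfg@orientationMu <- plan$mu[i]
    generateFiberImage(cfg, seed = plan$seed[i],
                       sourceId = plan$source_id[i])
  })
  attr(imgs, "truth") <- plan
  imgs
}

#' Write a synthetic cohort to disk
#'
#' Writes `n` TIFF tiles plus a ground-truth JSON sidecar
#' (`truth.json`) with the planted per-image parameters, for
#' planted-parameter recovery tests.
#'
#' @param presetName `"invasion"` or `"pseudoinvasion"`.
#' @param n number of tiles.
#' @param masterSeed integer seed.
#' @param outdir output directory (created if missing).
#' @param imageSize tile side in pixels.
#' @return character vector of the written TIFF paths, invisibly.
#' @export
simulateCohort <- function(presetName, n, masterSeed = 1L, outdir,
                           imageSize = 512L) {
  preset <- classPreset(presetName, imageSize = imageSize)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  imgs <- generateCohort(preset, n, masterSeed = masterSeed,
                         idPrefix = presetName)
  paths <- vapply(imgs, function(im) {
    p <- file.path(outdir, paste0(sourceId(im), ".tif"))
    writeSHGImage(im, p)
    p
  }, character(1))
  jsonlite::write_json(attr(imgs, "truth"),
                       file.path(outdir, "truth.json"),
                       dataframe = "rows", digits = NA)
  invisible(paths)
}
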
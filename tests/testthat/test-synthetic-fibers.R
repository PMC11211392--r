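test_that("generation is deterministic given (config, seed)", {
  cfg <- fiberFieldConfig(imageSize = 64, nFibers = 10, lengthMean = 30,
                          lengthSd = 8)
  a <- generateFiberImage(cfg, seed = 123)
  b <- generateFiberImage(cfg, seed = 123)
  expect_identical(pixels(a), pixels(b))
  c <- generateFiberImage(cfg, seed = 124)
  expect_false(identical(pixels(a), pixels(c)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generateFiberImage(fiberFieldConfig(imageSize = 64)))
  expect_identical(rnorm(1), before)
})

test_that("an empty field is background noise with near-zero TC-ratio", {
  cfg <- fiberFieldConfig(imageSize = 128, nFibers = 0)
  img <- generateFiberImage(cfg, seed = 9)
  expect_lt(abs(mean(pixels(img)) - cfg@backgroundLevel), 2)
  res <- thresholdImage(img)
  expect_lt(res$tc_ratio, 0.25)  # noise-only tail above the threshold
})

test_that("strong planted alignment is recovered by the orientation index", {
  cfg <- fiberFieldConfig(imageSize = 256, nFibers = 100, lengthMean = 200,
                          lengthSd = 40, width = 2, orientationMu = 0,
                          orientationKappa = 1000, curvatureJitter = 0.5,
                          fiberIntensity = 200, psfSigma = 0.6)
  o <- orientationIndex(generateFiberImage(cfg, seed = 3))
  expect_gte(o$N, 0.5)
  # spectrum elongates perpendicular to the mu = 0 fiber axis
  expect_lt(abs(abs(o$theta) - 90), 10)
})

test_that("class presets satisfy the documented ordering", {
  inv <- classPreset("invasion")
  psi <- classPreset("pseudoinvasion")
  expect_gt(inv@nFibers, psi@nFibers)
  expect_gt(inv@lengthMean, psi@lengthMean)
  expect_gt(inv@orientationKappa, psi@orientationKappa)
  expect_error(classPreset("carcinoma"), "should be one of")
})

test_that("cohorts are reproducible, distinct, and carry ground truth", {
  preset <- classPreset("pseudoinvasion", imageSize = 96)
  co1 <- generateCohort(preset, 3, masterSeed = 42)
  co2 <- generateCohort(preset, 3, masterSeed = 42)
  expect_length(co1, 3)
  for (i in 1:3)
    expect_identical(pixels(co1[[i]]), pixels(co2[[i]]))
  expect_false(identical(pixels(co1[[1]]), pixels(co1[[2]])))
  truth <- attr(co1, "truth")
  expect_true(all(c("seed", "nFibers", "kappa", "mu") %in% names(truth)))
  expect_true(all(truth$nFibers >= floor(preset@nFibers * 0.85)))
})

test_that("different master seeds give different images, similar statistics", {
  preset <- classPreset("pseudoinvasion", imageSize = 128)
  coA <- generateCohort(preset, 12, masterSeed = 7)
  coB <- generateCohort(preset, 12, masterSeed = 8)
  expect_false(identical(pixels(coA[[1]]), pixels(coB[[1]])))
  mA <- vapply(coA, function(im) mean(pixels(im)), numeric(1))
  mB <- vapply(coB, function(im) mean(pixels(im)), numeric(1))
  expect_gt(studentsT(mA, mB)$p, 0.01)
})

test_that("TC-ratio rises with planted fiber density", {
  densities <- c(10, 30, 90)
  tc <- vapply(densities, function(nf) {
    cfg <- fiberFieldConfig(imageSize = 128, nFibers = nf,
                            lengthMean = 40, lengthSd = 10)
    mean(vapply(1:5, function(s)
      thresholdImage(generateFiberImage(cfg, seed = 500 + s))$tc_ratio,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(tc) > 0))
})

test_that("invasion cohorts exceed pseudoinvasion in TC-ratio, mean and SD", {
  nInv <- measureImages(generateCohort(classPreset("invasion", 256), 6,
                                       masterSeed = 31))
  nPsi <- measureImages(generateCohort(classPreset("pseudoinvasion", 256), 6,
                                       masterSeed = 32))
  expect_gt(mean(nInv$tc_ratio), mean(nPsi$tc_ratio))
  expect_gt(mean(nInv$mean), mean(nPsi$mean))
  expect_gt(mean(nInv$sd), mean(nPsi$sd))
})

test_that("simulateCohort writes TIFFs plus a truth sidecar, reproducibly", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- simulateCohort("invasion", 2, masterSeed = 5, outdir = d1,
                       imageSize = 64)
  expect_length(p1, 2)
  expect_true(all(file.exists(p1)))
  expect_true(file.exists(file.path(d1, "truth.json")))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(nrow(truth), 2)
  p2 <- simulateCohort("invasion", 2, masterSeed = 5, outdir = d2,
                       imageSize = 64)
  expect_identical(readBin(p1[1], "raw", 1e6), readBin(p2[1], "raw", 1e6))
  img <- readSHGImage(p1[1])
  expect_identical(dim(img), c(64L, 64L))
})
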
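test_that("D'Agostino-Pearson reproduces reference values on frozen samples", {
  # expected values computed once with an independent implementation of
  # the same omnibus statistic and frozen here
  set.seed(123); x1 <- as.numeric(sprintf("%.12g", rnorm(50)))
  r1 <- dagostinoPearson(x1)
  expect_equal(r1$K2, 0.4519345521, tolerance = 1e-9)
  expect_equal(r1$p, 0.7977442066, tolerance = 1e-9)
  expect_equal(r1$Zg1, 0.5372587560, tolerance = 1e-9)
  expect_equal(r1$Zg2, -0.4040885809, tolerance = 1e-9)

  set.seed(99); x2 <- as.numeric(sprintf("%.12g", rexp(100)))
  r2 <- dagostinoPearson(x2)
  expect_equal(r2$K2, 61.2566333288, tolerance = 1e-9)
  expect_equal(r2$Zg1, 6.2539028802, tolerance = 1e-9)
  expect_equal(r2$Zg2, 4.7058827114, tolerance = 1e-9)
})

test_that("the omnibus test holds its size under the null", {
  rejections <- vapply(1:200, function(s) {
    set.seed(s)
    dagostinoPearson(rnorm(10000))$p <= 0.05
  }, logical(1))
  # nominal size 5%; allow 3 binomial SDs over 200 replicates
  expect_lte(mean(rejections), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("the omnibus test has power against heavy skew", {
  set.seed(7)
  expect_lt(dagostinoPearson(rexp(200))$p, 0.01)
})

test_that("a perfectly symmetric sample kills the skewness term", {
  set.seed(8)
  half <- rnorm(50)
  x <- c(half, -half)  # exactly mirror-symmetric
  expect_equal(dagostinoPearson(x)$Zg1, 0)
})

test_that("guard rails: small or constant samples are rejected", {
  expect_error(dagostinoPearson(rnorm(10)), "insufficient")
  expect_error(dagostinoPearson(rep(1, 30)), "variance")
})

test_that("pooled t on a hand-computed example", {
  r <- studentsT(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(r$t, -1)
  expect_equal(r$df, 8)
  expect_equal(r$p, 2 * pt(-1, 8))
})

test_that("identical groups give t = 0, p = 1; degenerate cases error", {
  x <- c(1, 5, 9, 2)
  r <- studentsT(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- studentsT(c(3, 3, 3), c(3, 3, 3))
  expect_equal(r2$p, 1)
  expect_error(studentsT(c(3, 3), c(4, 4)), "zero pooled variance")
})

test_that("t-test p agrees with a Monte-Carlo permutation oracle", {
  set.seed(55)
  for (k in 1:5) {
    a <- rnorm(8); b <- rnorm(8, mean = runif(1, 0, 1.5))
    pT <- studentsT(a, b)$p
    pPerm <- permutationP(a, b, B = 20000)
    expect_lt(abs(pT - pPerm), 0.05)
  }
})

test_that("swapping groups flips t and preserves p", {
  set.seed(56)
  a <- rnorm(12); b <- rnorm(15, 0.4)
  r1 <- studentsT(a, b); r2 <- studentsT(b, a)
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
})

test_that("tier mapping follows the star convention", {
  expect_identical(significanceTier(0.2), "ns")
  expect_identical(significanceTier(0.049), "*")
  expect_identical(significanceTier(0.009), "**")
  expect_identical(significanceTier(0.0009), "***")
  expect_identical(significanceTier(0.00009), "****")
})

makeTable <- function(n, shift = 0, seed = 1) {
  set.seed(seed)
  tab <- data.frame(source_id = sprintf("img_%03d", seq_len(n)))
  for (nm in parameterNames()) tab[[nm]] <- rnorm(n, mean = shift)
  tab
}

test_that("a table compared with itself yields no significance", {
  tab <- makeTable(30)
  cmp <- compareParameterTables(tab, tab)
  expect_equal(nrow(cmp), 12)
  expect_true(all(cmp$p_value == 1))
  expect_identical(attr(cmp, "n_significant"), 0L)
  expect_true(all(cmp$tier == "ns"))
})

test_that("an overwhelming shift makes all 12 parameters significant", {
  cmp <- compareParameterTables(makeTable(30, 0, seed = 2),
                                makeTable(30, 5, seed = 3))
  expect_identical(attr(cmp, "n_significant"), 12L)
  expect_true(all(cmp$tier == "****"))
  expect_true(all(cmp$n1 == 30 & cmp$n2 == 30))
  # group-mean CIs from the t distribution
  i <- which(cmp$parameter == "mean")
  set.seed(2); v <- rnorm(30)
  expect_equal(cmp$ci95_1[i], qt(0.975, 29) * sd(v) / sqrt(30))
})

test_that("undefined sentinels are dropped per parameter", {
  tabA <- makeTable(25, seed = 4); tabB <- makeTable(25, 3, seed = 5)
  tabA$skewness[1:5] <- NA
  expect_message(cmp <- compareParameterTables(tabA, tabB), "dropped 5")
  i <- which(cmp$parameter == "skewness")
  expect_equal(cmp$n1[i], 20)
  tabA$kurtosis[1:24] <- NA  # only 1 defined value left
  cmp2 <- suppressMessages(compareParameterTables(tabA, tabB))
  j <- which(cmp2$parameter == "kurtosis")
  expect_identical(cmp2$tier[j], "insufficient data")
  expect_true(is.na(cmp2$p_value[j]))
})

test_that("null calibration: about 5% false positives per parameter", {
  pvals <- vapply(1:400, function(s) {
    set.seed(1e6 + s)
    studentsT(rnorm(20), rnorm(20))$p
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.025)
})
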
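#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the z-transforms of sample skewness (D'Agostino 1970) and
#' kurtosis (Anscombe-Glynn 1983) into the omnibus statistic
#' \eqn{K^2 = Z(g_1)^2 + Z(g_2)^2}, referred to a chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param x numeric vector, `n >= 20` (the kurtosis z-transform is
#'   unreliable below that).
#' @return list with `K2`, `p` (two-sided), `Zg1`, `Zg2`.
#' @export
dagostinoPearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 20L) stop("insufficient sample: D'Agostino-Pearson needs n >= 20")
  if (stats::var(x) == 0) stop("zero-variance sample")
  d <- x - mean(x)
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  g1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness z-transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- if (y == 0) 0 else delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z-transform (Anscombe-Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 *
    (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  denom <- 1 + xk * sqrt(2 / (A - 4))
  term <- sign(denom) * ((1 - 2 / A) / abs(denom))^(1 / 3)
  Zg2 <- ((1 - 2 / (9 * A)) - term) / sqrt(2 / (9 * A))

  K2 <- Zg1^2 + Zg2^2
  list(K2 = K2, p = stats::pchisq(K2, df = 2, lower.tail = FALSE),
       Zg1 = Zg1, Zg2 = Zg2)
}

#' Unpaired Student's t-test (pooled variance)
#'
#' Classic two-sample pooled-variance t with two-sided p and
#' `df = n1 + n2 - 2`. Welch's unequal-variance form is available via
#' `welch = TRUE`.
#'
#' @param groupA,groupB numeric vectors, each `n >= 2`.
#' @param welch use Welch's correction instead of pooling.
#' @return list with `t`, `p`, `df`.
#' @export
studentsT <- function(groupA, groupB, welch = FALSE) {
  groupA <- as.numeric(groupA); groupB <- as.numeric(groupB)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("both groups need at least 2 observations")
  if (stats::var(groupA) + stats::var(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, p = 1,
                  df = length(groupA) + length(groupB) - 2))
    stop("zero pooled variance with unequal means")
  }
  tt <- stats::t.test(groupA, groupB, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Significance tier from a p-value
#'
#' Star convention: `ns` for p >= 0.05, then `*`, `**`, `***`, `****`
#' at cutpoints 0.05, 0.01, 0.001, 0.0001.
#'
#' @param p p-value in `[0, 1]`.
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
significanceTier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.0001) "****"
  else if (p < 0.001) "***"
  else if (p < 0.01) "**"
  else if (p < 0.05) "*"
  else "ns"
}

#' Compare two per-image parameter tables
#'
#' For each of the twelve canonical parameters: drops undefined (`NA`)
#' rows, runs the unpaired Student's t-test between the groups, computes
#' group means with t-distribution 95% confidence half-widths, assesses
#' per-group normality by [dagostinoPearson()] (when `n >= 20`), and
#' assigns a significance tier. No multiple-testing correction is
#' applied by default; Bonferroni or Holm adjustment of the p-values is
#' available through `adjust`.
#'
#' @param tableA,tableB data.frames as returned by [measureImages()] /
#'   [readParameterTable()].
#' @param alpha significance threshold (default 0.05).
#' @param welch use Welch's t instead of the pooled form.
#' @param adjust `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return data.frame with one row per parameter (columns `parameter`,
#'   `n1`, `n2`, `mean1`, `mean2`, `ci95_1`, `ci95_2`, `t_stat`,
#'   `p_value`, `normal1`, `normal2`, `tier`) and attribute
#'   `n_significant`, the number of parameters with `p < alpha`.
#' @export
compareParameterTables <- function(tableA, tableB, alpha = 0.05,
                                   welch = FALSE,
                                   adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  pars <- parameterNames()
  for (tab in list(tableA, tableB)) {
    missing <- setdiff(pars, names(tab))
    if (length(missing))
      stop("parameter table lacks column(s): ",
           paste(missing, collapse = ", "))
  }
  ci95 <- function(v) {
    n <- length(v)
    if (n < 2L) return(NA_real_)
    stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n)
  }
  normalFlag <- function(v) {
    if (length(v) < 20L || stats::var(v) == 0) return(NA)
    dagostinoPearson(v)$p > 0.05
  }
  rows <- lapply(pars, function(nm) {
    a <- tableA[[nm]]; b <- tableB[[nm]]
    nDropped <- sum(is.na(a)) + sum(is.na(b))
    if (nDropped > 0)
      message(sprintf("parameter '%s': dropped %d undefined value(s)",
                      nm, nDropped))
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 3L || length(b) < 3L) {
      return(data.frame(parameter = nm, n1 = length(a), n2 = length(b),
                        mean1 = NA_real_, mean2 = NA_real_,
                        ci95_1 = NA_real_, ci95_2 = NA_real_,
                        t_stat = NA_real_, p_value = NA_real_,
                        normal1 = NA, normal2 = NA,
                        tier = "insufficient data",
                        stringsAsFactors = FALSE))
    }
    tt <- studentsT(a, b, welch = welch)
    data.frame(parameter = nm, n1 = length(a), n2 = length(b),
               mean1 = mean(a), mean2 = mean(b),
               ci95_1 = ci95(a), ci95_2 = ci95(b),
               t_stat = tt$t, p_value = tt$p,
               normal1 = normalFlag(a), normal2 = normalFlag(b),
               tier = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p_value)
  if (adjust != "none")
    out$p_value[ok] <- stats::p.adjust(out$p_value[ok], method = adjust)
  out$tier[ok] <- vapply(out$p_value[ok], significanceTier, character(1))
  attr(out, "n_significant") <- sum(out$p_value[ok] < alpha)
  out
}
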
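# Independent brute-force oracles and fixture builders used across the
# suite. These deliberately re-derive each quantity by the slowest,
# most literal route so they share no code path with the package.

# Triangle threshold by exhaustive point-to-line distance maximization.
triangleOracle <- function(counts) {
  peak <- which.max(counts)
  nz <- which(counts > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  right <- (hi - peak) >= (peak - lo)
  tail_end <- if (right) hi else lo
  p1 <- c(peak, counts[peak]); p2 <- c(tail_end, counts[tail_end])
  seg <- p2 - p1
  cand <- setdiff(seq(min(peak, tail_end), max(peak, tail_end)),
                  c(peak, tail_end))
  cand <- cand[order(abs(cand - peak))]  # ties resolve toward the peak
  best <- NA_integer_; bestD <- -Inf
  for (b in cand) {
    v <- c(b, counts[b]) - p1
    d <- abs(seg[1] * v[2] - seg[2] * v[1]) / sqrt(sum(seg^2))
    if (d > bestD) { bestD <- d; best <- b }
  }
  best - 1L
}

# GLCM by literal nested loops over every pixel pair.
glcmOracle <- function(m, dr, dc, L) {
  cnt <- matrix(0, L, L)
  for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nrow(m) && c2 >= 1 && c2 <= ncol(m)) {
      i <- m[r, c] + 1; j <- m[r2, c2] + 1
      cnt[i, j] <- cnt[i, j] + 1
      cnt[j, i] <- cnt[j, i] + 1
    }
  }
  cnt / sum(cnt)
}

# The five texture features by a literal double loop.
glcmFeaturesOracle <- function(p) {
  L <- nrow(p)
  contrast <- homog <- energy <- entropy <- 0
  mu_i <- mu_j <- 0
  for (i in 1:L) for (j in 1:L) {
    pij <- p[i, j]
    contrast <- contrast + pij * (i - j)^2
    homog <- homog + pij / (1 + (i - j)^2)
    energy <- energy + pij^2
    if (pij > 0) entropy <- entropy - pij * log2(pij)
    mu_i <- mu_i + (i - 1) * pij
    mu_j <- mu_j + (j - 1) * pij
  }
  var_i <- var_j <- corr <- 0
  for (i in 1:L) for (j in 1:L) {
    var_i <- var_i + (i - 1 - mu_i)^2 * p[i, j]
    var_j <- var_j + (j - 1 - mu_j)^2 * p[i, j]
  }
  for (i in 1:L) for (j in 1:L)
    corr <- corr + (i - 1 - mu_i) * (j - 1 - mu_j) * p[i, j]
  corr <- corr / sqrt(var_i * var_j)
  list(contrast = contrast, homogeneity = homog, energy = energy,
       entropy = entropy, correlation = corr)
}

# Box counting by explicit iteration over every grid cell.
boxCountOracle <- function(mask, s) {
  nr <- nrow(mask); nc <- ncol(mask)
  n <- 0L
  for (r0 in seq(1, nr, by = s)) for (c0 in seq(1, nc, by = s)) {
    blk <- mask[r0:min(r0 + s - 1, nr), c0:min(c0 + s - 1, nc)]
    if (any(blk)) n <- n + 1L
  }
  n
}

# Monte-Carlo permutation p-value for the difference in means.
permutationP <- function(a, b, B = 20000) {
  obs <- abs(mean(a) - mean(b))
  pool <- c(a, b); na <- length(a)
  hits <- 0L
  for (k in seq_len(B)) {
    idx <- sample(length(pool), na)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# Population moments by a literal loop.
momentsOracle <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- m3 <- m4 <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2 / n; m3 <- m3 + d^3 / n; m4 <- m4 + d^4 / n
  }
  list(mean = mu, sd = sqrt(m2), skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3)
}

# Sierpinski carpet as a logical matrix of side 3^depth.
sierpinskiCarpet <- function(depth) {
  m <- matrix(TRUE, 1, 1)
  for (k in seq_len(depth)) {
    n <- nrow(m)
    big <- matrix(FALSE, 3 * n, 3 * n)
    for (br in 0:2) for (bc in 0:2) {
      if (br == 1 && bc == 1) next
      big[br * n + 1:n, bc * n + 1:n] <- m
    }
    m <- big
  }
  m
}

# An 8x8-or-larger checkerboard of two intensities.
checkerboard <- function(n = 8, lo = 0, hi = 1) {
  outer(1:n, 1:n, function(r, c) ifelse((r + c) %% 2 == 0, lo, hi)) * 1.0
}

# Random histogram with a clear unimodal peak. Continuous counts keep
# the peak and the perpendicular distances almost surely untied, so
# geometric properties (mirroring) are unambiguous.
randomHistogram <- function(nbins = 256) {
  peak <- sample(40:215, 1)
  x <- seq_len(nbins)
  h <- 1000 * exp(-(x - peak)^2 / (2 * runif(1, 5, 30)^2)) +
    200 * exp(-(x - peak)^2 / (2 * runif(1, 40, 80)^2))
  h + runif(nbins, 0, 5)
}
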
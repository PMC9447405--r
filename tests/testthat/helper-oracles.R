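# Independent brute-force Otsu: direct evaluation of the between-class
# variance at every candidate split, with explicit per-class sums (no
# cumulative-array tricks shared with the implementation).
bruteForceOtsu <- function(counts, binWidth = 1L) {
  total <- sum(counts)
  v <- (0:255) * binWidth + (binWidth - 1) / 2
  best <- -Inf
  bestT <- NA_integer_
  for (t in 0:254) {
    lo <- 1:(t + 1L)
    hi <- (t + 2L):256
    n0 <- sum(counts[lo]); n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[lo] * v[lo]) / n0
    mu1 <- sum(counts[hi] * v[hi]) / n1
    sb <- (n0 / total) * (n1 / total) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; bestT <- t }
  }
  if (is.na(bestT)) return(NA_real_)
  (bestT + 1) * binWidth - 1
}

# Random 256-bin histogram: 1-3 Gaussian-ish clusters of pixel values.
# Guaranteed non-degenerate (>= 2 occupied bins).
randomClusterHistogram <- function() {
  repeat {
    k <- sample(1:3, 1)
    centers <- sample(10:245, k)
    sds <- runif(k, 2, 25)
    w <- as.vector(stats::rmultinom(1, 2000, rep(1, k)))
    px <- unlist(lapply(seq_len(k), function(i)
      round(rnorm(w[i], centers[i], sds[i]))))
    px <- pmin(pmax(px, 0), 255)
    counts <- tabulate(px + 1L, nbins = 256L)
    if (sum(counts > 0L) >= 2L) return(counts)
  }
}

# tiny flat grey fixture with one centred square spot, for hand-checkable
# quantification cases
squareSpotCell <- function(size = 20L, bg = 20, amp = 180, half = 4L) {
  px <- matrix(bg, size, size)
  c0 <- size %/% 2L
  px[(c0 - half):(c0 + half), (c0 - half):(c0 + half)] <- bg + amp
  px
}
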
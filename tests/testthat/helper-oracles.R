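# Independent oracles, deliberately naive: plain loops and enumeration,
# sharing no code with the package implementation.

# exhaustive Otsu: scan every threshold, recompute class stats from scratch
brute_otsu <- function(counts) {
  n <- sum(counts)
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:254) {
    idx0 <- 1:(t + 1)                  # intensities 0..t
    w0 <- sum(counts[idx0]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[idx0] * (idx0 - 1)) / w0
    mu1 <- sum(counts[-idx0] * ((1:256)[-idx0] - 1)) / w1
    v <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    if (v > best_v + 1e-9 * max(1, abs(v))) { best_v <- v; best_t <- t }
  }
  best_t
}

# cumulative-statistic oracle: walk the sorted sequence and accumulate
brute_half_cumulation <- function(values) {
  v <- sort(values)
  total <- sum(v)
  acc <- 0
  for (k in seq_along(v)) {
    acc <- acc + v[k]
    if (acc / total >= 0.5) return(list(value = v[k], rank = k))
  }
}

# random blobby binary mask for conservation / labeling properties
random_mask <- function(h = 40, w = 40, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

# histogram with a few random modes so optima are non-trivial
random_histogram <- function() {
  k <- sample(2:5, 1)
  centers <- sample(0:255, k)
  counts <- tabulate(
    pmin(pmax(round(rnorm(500, rep(centers, each = 100), 20)), 0), 255) + 1L,
    nbins = 256L)
  counts + tabulate(sample(0:255, 50, replace = TRUE) + 1L, nbins = 256L)
}
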
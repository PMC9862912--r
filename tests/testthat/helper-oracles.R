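# Independent brute-force oracles used across the suite.  These are kept
# deliberately literal (scalar loops, direct formula transcriptions) so
# they share no code path with the package implementations they check.

# raw-periodogram band power (Hann window), per unit bandwidth
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
  X <- fft(x * w)
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f <= band[2]
  mean(Mod(X[sel])^2)
}

# scalar-loop exponential moving standardization (clip with pre-update
# stats, update mean then variance with the clipped value, emit with the
# updated stats)
oracle_ems <- function(x, mu0, var0, lambda, clip, floor) {
  mu <- mu0; v <- max(var0, floor)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    s <- sqrt(v)
    xi <- min(max(x[i], mu - clip * s), mu + clip * s)
    mu <- lambda * mu + (1 - lambda) * xi
    v <- lambda * v + (1 - lambda) * (xi - mu)^2
    out[i] <- (xi - mu) / sqrt(max(v, floor))
  }
  out
}

oracle_entropy_bits <- function(p) {
  h <- 0
  for (pj in p) if (pj > 1e-12) h <- h - pj * log2(pj)
  h
}

oracle_mutual_information <- function(stack) {
  ystar <- numeric(ncol(stack))
  for (j in seq_len(ncol(stack))) ystar[j] <- mean(stack[, j])
  acc <- 0
  for (t in seq_len(nrow(stack))) acc <- acc + oracle_entropy_bits(stack[t, ])
  oracle_entropy_bits(ystar) - acc / nrow(stack)
}

oracle_margin <- function(stack) {
  ystar <- colSums(stack) / nrow(stack)
  cls <- which(ystar == max(ystar))[1]
  d <- numeric(nrow(stack))
  for (t in seq_len(nrow(stack))) {
    best_other <- -Inf
    for (j in seq_len(ncol(stack))) if (j != cls) best_other <- max(best_other, stack[t, j])
    d[t] <- stack[t, cls] - best_other
  }
  list(M = mean(d), sigma_d = sqrt(sum((d - mean(d))^2) / (length(d) - 1)))
}

# exhaustive UA evaluation over the grid, O(n * grid)
oracle_sweep <- function(Hn, correct, grid) {
  best_th <- NA; best_ua <- -Inf
  ua <- numeric(length(grid))
  for (g in seq_along(grid)) {
    ncc <- nic <- ncu <- niu <- 0
    for (i in seq_along(Hn)) {
      certain <- Hn[i] <= grid[g]
      if (correct[i] && certain) ncc <- ncc + 1
      else if (!correct[i] && certain) nic <- nic + 1
      else if (correct[i] && !certain) ncu <- ncu + 1
      else niu <- niu + 1
    }
    ua[g] <- (ncc + niu) / length(Hn)
    if (ua[g] > best_ua) { best_ua <- ua[g]; best_th <- grid[g] }
  }
  list(best_th = best_th, best_ua = best_ua, ua = ua)
}

random_stack <- function(T = 20, C = 4) {
  g <- matrix(rgamma(T * C, shape = runif(C, 0.3, 4)), T, C, byrow = FALSE)
  g / rowSums(g)
}

tiny_arch <- function(n_channels = 2, n_classes = 2)
  architecture_spec(n_channels, n_classes, input_len = 60,
                    temporal_filter_len = 7, n_filters = 3,
                    temporal_stride = 2, avg_pool_len = 5,
                    max_pool_len = 2, max_pool_stride = 2, dropout = 0)

# crops for the tiny architecture: class k has oscillation amplitude
# scaled by k on channel 1, trivially separable by log band power
tiny_crop_data <- function(n_per_class = 40, n_classes = 2, seed = 1) {
  set.seed(seed)
  n <- n_per_class * n_classes
  labels <- rep(seq_len(n_classes), n_per_class)
  crops <- array(0, dim = c(n, 2, 60))
  tt <- seq_len(60) / 60
  for (i in seq_len(n)) {
    amp <- labels[i]
    crops[i, 1, ] <- amp * sin(2 * pi * 8 * tt + runif(1, 0, 2 * pi)) +
      0.3 * rnorm(60)
    crops[i, 2, ] <- 0.3 * rnorm(60)
  }
  list(crops = crops, labels = labels)
}
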
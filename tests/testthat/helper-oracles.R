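# Independent oracles used across the suite. Each reimplements the checked
# quantity by the most literal route available (full sort, direct
# convolution sums, closed-form normal equations, dense grid scans) and
# never calls the package path it verifies.

# median of the n largest values by full sort and explicit midpoint rule
oracle_medmax <- function(v, n = 20L) {
  s <- rev(sort(v))
  k <- min(n, length(v))
  top <- sort(s[seq_len(k)])
  if (k %% 2L == 1L) top[(k + 1L) / 2L] else (top[k / 2L] + top[k / 2L + 1L]) / 2
}

# reflective index fold (half-sample symmetric extension), 0-based
oracle_fold <- function(i, n) {
  p <- i %% (2L * n)
  ifelse(p >= n, 2L * n - 1L - p, p)
}

# direct separable Gaussian convolution with reflective borders; kernel is
# the sampled, normalized Gaussian truncated at 4 sigma (the filter's
# stated definition), but applied by explicit per-pixel sums
oracle_gauss_blur <- function(frame, sigma_px) {
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  w <- stats::dnorm(-r:r, sd = sigma_px)
  w <- w / sum(w)
  H <- nrow(frame); W <- ncol(frame)
  tmp <- matrix(0, H, W)
  for (i in seq_len(H)) {
    idx <- oracle_fold((i - 1L) + (-r:r), H) + 1L
    tmp[i, ] <- colSums(frame[idx, , drop = FALSE] * w)
  }
  out <- matrix(0, H, W)
  for (j in seq_len(W)) {
    idx <- oracle_fold((j - 1L) + (-r:r), W) + 1L
    out[, j] <- rowSums(sweep(tmp[, idx, drop = FALSE], 2, w, `*`))
  }
  out
}

oracle_dog <- function(frame, p) {
  oracle_gauss_blur(frame, p$sigma_small_px) -
    oracle_gauss_blur(frame, p$sigma_large_px)
}

# closed-form simple least squares via the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum((y - intercept - slope * x)^2) / sst
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# brute-force scan for the half-maximum time at 1e-5 s resolution
oracle_t50_scan <- function(p, t_end = 60, step = 1e-5) {
  t <- seq(0, t_end, by = step)
  f <- recruitment_fraction(t, p)
  t[which(f >= 0.5 * max(f))[1]]
}
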
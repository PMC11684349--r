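# Independent oracles, deliberately written from the closed-form definitions
# rather than through the package's code paths.

# Direct-formula recomputation of the 12 window features. Uses e1071 for the
# moment statistics and an explicit DFT (outer-product trig sums) for the
# periodogram, so no code is shared with extract_features().
feature_oracle <- function(x, rate, bands = default_bands(rate), bins = 16L) {
  n <- length(x)
  m <- sum(x) / n
  out <- c(
    mean = m,
    variance = sum((x - m)^2) / (n - 1),
    rms = sqrt(sum(x^2) / n),
    skewness = if (stats::var(x) == 0) 0 else e1071::skewness(x, type = 1),
    kurtosis = if (stats::var(x) == 0) 0 else e1071::kurtosis(x, type = 1),
    entropy = {
      rg <- range(x)
      if (rg[1] == rg[2]) 0 else {
        h <- hist(x, breaks = seq(rg[1], rg[2], length.out = bins + 1L),
                  plot = FALSE)
        p <- h$counts[h$counts > 0] / n
        -sum(p * log(p))
      }
    },
    mad1 = mean(abs(diff(x))),
    mad2 = mean(abs(diff(x, differences = 2)))
  )
  xc <- x - m
  nf <- n %/% 2
  j <- seq_len(nf)
  ang <- outer(j, 0:(n - 1)) * (-2 * pi / n)
  re <- as.vector(cos(ang) %*% xc)
  im <- as.vector(sin(ang) %*% xc)
  P <- (re^2 + im^2) / n
  freqs <- j * rate / n
  bp <- vapply(seq_len(nrow(bands)), function(b) {
    sel <- freqs > bands[b, "lo"] & freqs <= bands[b, "hi"]
    if (any(sel)) sum(P[sel]) else 0
  }, numeric(1))
  names(bp) <- paste0("bp", seq_len(nrow(bands)))
  c(out, bp)
}

# Brute-force enumeration of valid window start positions.
segment_count_oracle <- function(len, window, overlap) {
  stride <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- integer(0)
  s <- 1L
  while (s + window - 1L <= len) {
    starts <- c(starts, s)
    s <- s + stride
  }
  starts
}

# Rank-based AUC by explicit pair counting.
auc_oracle <- function(y, score) {
  pos <- score[y == 1]; neg <- score[y == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
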
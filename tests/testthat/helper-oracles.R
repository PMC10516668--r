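# Independent oracles, written against first principles and kept free of the
# package's own code paths.

# exhaustive-enumeration hypergeometric upper tail: P(X >= k)
enumHyperP <- function(M, n, N, k) {
  xs <- k:min(n, N)
  sum(choose(n, xs) * choose(M - n, N - xs)) / choose(M, N)
}

# recursive Grubbs decisions from scratch: returns indices (into the original
# vector) that an iterative two-sided single-outlier filter removes
grubbsOracleRemoved <- function(x, alpha = 0.05) {
  removed <- integer()
  idx <- seq_along(x)
  while (length(x) >= 3 && !isTRUE(all.equal(stats::sd(x), 0)) &&
         stats::sd(x) > 0) {
    n <- length(x)
    m <- sum(x) / n
    s <- sqrt(sum((x - m)^2) / (n - 1))
    G <- max(abs(x - m)) / s
    tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
    crit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (G <= crit) break
    i <- which.max(abs(x - m))
    removed <- c(removed, idx[i])
    x <- x[-i]
    idx <- idx[-i]
  }
  removed
}

# brute-force Benjamini-Hochberg step-up with monotonicity enforcement
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  qsorted <- p[o] * n / seq_len(n)
  for (i in seq_len(n)) qsorted[i] <- min(qsorted[i:n])
  q[o] <- pmin(qsorted, 1)
  q
}

# rasterized pixel count of a disc: direct count over the integer grid
discPixelCount <- function(cy, cx, radius, H, W) {
  ys <- 0:(H - 1); xs <- 0:(W - 1)
  sum(outer((ys - cy)^2, (xs - cx)^2, "+") <= radius^2)
}

# standard hexcone HSV conversion for a single 8-bit pixel
hsvOracle <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b)
  V <- mx / 255
  S <- if (mx == 0) 0 else (mx - mn) / mx
  c(S = S, V = V)
}
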
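# Independent brute-force oracles. These deliberately re-derive each
# operation from its definition with different code paths than the
# implementation (explicit loops, lm fits, dense grids).

# Weighted least squares via stats::lm (and through the origin).
oracle_wls <- function(bx, by, w, intercept = TRUE) {
  fit <- if (intercept) stats::lm(by ~ bx, weights = w)
         else stats::lm(by ~ 0 + bx, weights = w)
  stats::coef(fit)
}

# First-wins duplicate scan.
oracle_first_wins <- function(ids) {
  seen <- character(0)
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    keep[i] <- !(ids[i] %in% seen)
    seen <- c(seen, ids[i])
  }
  keep
}

# Greedy clumping, explicit double loop over candidates.
oracle_clump <- function(id, p, chrom, pos, r, r2max, window) {
  # r: matrix with dimnames = ids
  remaining <- order(p, id)
  kept <- character(0)
  while (length(remaining)) {
    i <- remaining[1]
    kept <- c(kept, id[i])
    drop <- i
    for (j in remaining[-1]) {
      if (chrom[j] == chrom[i] && abs(pos[j] - pos[i]) <= window) {
        rij <- r[id[i], id[j]]
        if (rij^2 > r2max) drop <- c(drop, j)
      }
    }
    remaining <- setdiff(remaining, drop)
  }
  kept
}

# Benjamini-Hochberg q-values from the step-up definition, double loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, m * p[o[j]] / j)
    q_sorted[i] <- min(1, min(vals))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Weighted median by explicit interpolation arithmetic.
oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(theta[1])
  n <- length(theta)
  if (s[n] <= 0.5) return(theta[n])
  below <- max(which(s < 0.5))
  theta[below] + (theta[below + 1] - theta[below]) *
    (0.5 - s[below]) / (s[below + 1] - s[below])
}

# Kernel-density mode on a dense 10,001-point grid.
oracle_mode <- function(theta, w, phi = 1) {
  k <- length(theta)
  spread <- min(stats::sd(theta), stats::IQR(theta) / 1.349)
  if (spread == 0) spread <- stats::sd(theta)
  if (spread == 0) return(theta[1])
  bw <- phi * 0.9 * spread * k^(-1 / 5)
  grid <- seq(min(theta) - 3 * bw, max(theta) + 3 * bw, length.out = 10001)
  dens <- sapply(grid, function(g) sum(w * stats::dnorm(g, theta, bw)))
  grid[which.max(dens)]
}

# Cis filter as a plain double loop.
oracle_cis <- function(d, chrom, lo, hi, pmax) {
  out <- character(0)
  pv <- numeric(0)
  ps <- numeric(0)
  for (i in seq_len(nrow(d))) {
    if (d$chrom[i] == chrom && d$pos[i] >= lo && d$pos[i] <= hi &&
        d$pvalue[i] < pmax) {
      out <- c(out, d$variant_id[i])
      pv <- c(pv, d$pvalue[i])
      ps <- c(ps, d$pos[i])
    }
  }
  out[order(pv, ps)]
}
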
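# independent brute-force oracles used across tests

# pmf of total rounded column scores by exhaustive enumeration of all 4^w
# sequences; returns named vector keyed by integer grid index
enum_score_dist <- function(sm, model, epsilon) {
  w <- sm$width
  k <- round(sm$scores / epsilon)
  emis <- if (model == "background") matrix(sm$background, 4, w) else sm$motif_probs
  combos <- as.matrix(expand.grid(rep(list(1:4), w)))
  tot <- integer(nrow(combos))
  pr <- rep(1, nrow(combos))
  for (j in seq_len(w)) {
    tot <- tot + k[cbind(combos[, j], j)]
    pr <- pr * emis[cbind(combos[, j], j)]
  }
  out <- tapply(pr, tot, sum)
  out[order(as.integer(names(out)))]
}

# step-up BH by hand
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by hypergeometric enumeration over all tables
# with the observed margins
fisher_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), numeric(1))
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Clopper-Pearson bounds from binomial tail probabilities (no beta quantiles)
cp_oracle <- function(k, n, conf = 0.95) {
  alpha <- 1 - conf
  lo <- if (k == 0) 0 else
    uniroot(function(p) pbinom(k - 1, n, p, lower.tail = FALSE) - alpha / 2,
      c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - alpha / 2,
      c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lo = lo, hi = hi)
}

# quantile normalization by explicit per-column construction
qn_oracle <- function(mat) {
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    ord <- order(x)
    vals <- ref
    # ties: average the reference values the tied block spans
    xs <- x[ord]
    i <- 1
    while (i <= length(xs)) {
      jj <- i
      while (jj < length(xs) && xs[jj + 1] == xs[i]) jj <- jj + 1
      vals[i:jj] <- mean(ref[i:jj])
      i <- jj + 1
    }
    out[ord, j] <- vals
  }
  out
}

# mid-ranks by pair counting, then rank-sum of x
ranksum_oracle <- function(x, y) {
  v <- c(x, y)
  r <- vapply(v, function(vi) 1 + sum(v < vi) + (sum(v == vi) - 1) / 2,
    numeric(1))
  sum(r[seq_along(x)])
}

# Spearman rho with mid-rank ties via Pearson on oracle ranks
spearman_oracle <- function(x, y) {
  rx <- vapply(x, function(v) 1 + sum(x < v) + (sum(x == v) - 1) / 2, numeric(1))
  ry <- vapply(y, function(v) 1 + sum(y < v) + (sum(y == v) - 1) / 2, numeric(1))
  cor(rx, ry)
}

rand_pcm <- function(w, max_count = 30) {
  m <- matrix(sample(0:max_count, 4 * w, replace = TRUE), 4,
    dimnames = list(c("A", "C", "G", "T"), NULL))
  m[1, colSums(m) == 0] <- 1
  m
}

rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
    prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)), collapse = "")
}

# von Mises sampler (Best & Fisher) returning phases in hours on [0, 24)
rvonmises_hours <- function(n, mu_hours, kappa, period = 24) {
  mu <- mu_hours * 2 * pi / period
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2] > 0 || log(c_ / u[2]) + 1 - c_ >= 0) {
      theta <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- (theta %% (2 * pi)) * period / (2 * pi)
      i <- i + 1
    }
  }
  out
}

# genomic position of a TSS-relative offset (no position 0), test-side copy
offset_to_pos_for_test <- function(offset, tss, strand) {
  strand <- rep(strand, length.out = length(offset))
  ifelse(strand == "+", tss + offset - (offset > 0), tss - offset + (offset > 0))
}

circ_dist_hours <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  min(d, period - d)
}
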
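# Independent reference implementations used as oracles. These deliberately
# re-derive each quantity by the most literal route available (direct
# formula evaluation, triple loops, naive agglomeration, exhaustive
# enumeration) and stay independent of the package's code paths.

# biweight midcorrelation by direct evaluation of the weighting formula
oracle_bicor <- function(x, y) {
  w_of <- function(v) {
    med <- median(v)
    s <- median(abs(v - med))
    if (s == 0) return(v - mean(v))
    u <- (v - med) / (9 * s)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (v - med) * w
  }
  xt <- w_of(x); yt <- w_of(y)
  sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
}

# topological overlap by explicit triple loop
oracle_tom <- function(A) {
  diag(A) <- 0
  n <- nrow(A)
  k <- rowSums(A)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) { out[i, j] <- 1; next }
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
      den <- min(k[i], k[j]) + 1 - A[i, j]
      out[i, j] <- if (den <= 0) 0 else (l + A[i, j]) / den
    }
  }
  out
}

# naive average-linkage agglomeration: returns sorted merge heights
oracle_average_linkage_heights <- function(D) {
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        d <- mean(D[clusters[[a]], clusters[[b]]])
        if (d < best_d) { best_d <- d; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# adjusted Rand index from the explicit contingency-table formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); sa <- sum(ch2(rowSums(tab))); sb <- sum(ch2(colSums(tab)))
  exp_idx <- sa * sb / ch2(n)
  (sij - exp_idx) / ((sa + sb) / 2 - exp_idx)
}

# Benjamini-Hochberg step-up, written out literally
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# hypergeometric upper-tail p by exhaustive enumeration of all draws
oracle_hyper_enum <- function(universe_n, set_n, draw_n, min_overlap) {
  draws <- combn(universe_n, draw_n)
  hits <- colSums(draws <= set_n)   # genes 1..set_n form the set
  mean(hits >= min_overlap)
}

expect_symmetric_range <- function(M, lo, hi, tol = 1e-12) {
  expect_true(isSymmetric(unname(M), tol = 1e-8))
  expect_true(all(M >= lo - tol & M <= hi + tol, na.rm = TRUE))
}
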
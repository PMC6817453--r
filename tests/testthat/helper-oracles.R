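# Independent brute-force oracles. These deliberately avoid the package's
# implementation paths (and, where the implementation wraps a stats::
# routine, avoid that routine too).

# Kendall tau-b by exhaustive pair enumeration with tie corrections
oracle_tau_b <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 2 || length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  C <- D <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    if (x[i] == x[j]) tx <- tx + 1
    if (y[i] == y[j]) ty <- ty + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Spearman as Pearson on average-tie ranks, written out longhand
oracle_spearman <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2 || length(unique(x)) < 2 || length(unique(y)) < 2)
    return(NA_real_)
  r <- rank(x); s <- rank(y)
  rm <- r - mean(r); sm <- s - mean(s)
  sum(rm * sm) / sqrt(sum(rm^2) * sum(sm^2))
}

# two-sided Fisher exact by hypergeometric enumeration over the free cell
oracle_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == N || c1 == N) return(1)
  lo <- max(0, r1 + c1 - N); hi <- min(r1, c1)
  pr <- vapply(lo:hi, function(k)
    choose(c1, k) * choose(N - c1, r1 - k) / choose(N, r1), numeric(1))
  pObs <- pr[a - lo + 1]
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# exhaustive tail probability of the |pct difference| permutation statistic
oracle_perm_tail <- function(a, b) {
  pool <- c(a, b); n <- length(pool); nA <- length(a)
  obs <- abs(100 * mean(a) - 100 * mean(b))
  picks <- utils::combn(n, nA)
  stats <- apply(picks, 2, function(idx)
    abs(100 * mean(pool[idx]) - 100 * mean(pool[-idx])))
  mean(stats >= obs - 1e-9)
}

# complete-linkage merge heights from the definition: inter-cluster distance
# is the max ORIGINAL pairwise distance; same lexicographic tie rule
oracle_complete_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))   # member index sets
  created <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- NULL; bestD <- Inf
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        d <- max(D[clusters[[i]], clusters[[j]]])
        key <- sort(c(created[i], created[j]))
        better <- d < bestD - 1e-12 ||
          (abs(d - bestD) <= 1e-12 && !is.null(best) &&
             (key[1] < best$key[1] ||
                (key[1] == best$key[1] && key[2] < best$key[2])))
        if (is.null(best) || better) { best <- list(i = i, j = j, key = key); bestD <- d }
      }
    heights[step] <- bestD
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    created[best$i] <- n + step
    clusters[[best$j]] <- NULL
    created <- created[-best$j]
  }
  heights
}

# hand step-up BH adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    adj[o[k]] <- prev
  }
  pmin(adj, 1)
}
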
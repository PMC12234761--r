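# Brute-force enumeration oracles for the rank tests, written independently
# of the package implementations (matrix enumeration rather than bit masks /
# recursive combination walks).

oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  stats <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  mean(abs(stats - mu) >= abs(v - mu) - 1e-12)
}

oracle_mann_whitney_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_stat <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  # rank-based U is invariant to which elements go first; enumerate index sets
  sets <- utils::combn(n1 + n2, n1)
  r <- rank(pooled)
  stats <- apply(sets, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(stats - mu) >= abs(u - mu) - 1e-12)
}

oracle_kruskal_p <- function(groups) {
  n_i <- lengths(groups)
  n <- sum(n_i)
  pooled <- unlist(groups)
  r <- rank(pooled)
  grp <- rep(seq_along(groups), n_i)
  h_stat <- function(rr) {
    rs <- tapply(rr, grp, sum)
    h <- 12 / (n * (n + 1)) * sum(rs^2 / n_i) - 3 * (n + 1)
    tie_tab <- table(rr)
    corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
    if (corr > 0) h / corr else 0
  }
  h <- h_stat(r)
  # enumerate by permuting ranks across the fixed group layout; distinct
  # permutations of possibly tied ranks collapse, so weight via all perms of
  # a moderate n (n <= 8 here keeps 40320 permutations)
  perms <- permutations_of(n)
  stats <- vapply(seq_len(ncol(perms)), function(i) h_stat(r[perms[, i]]),
                  numeric(1))
  mean(stats >= h - 1e-12)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 1
  for (k in seq_len(n)) {
    for (j in seq_len(ncol(sub))) {
      rest <- setdiff(seq_len(n), k)
      out[, col] <- c(k, rest[sub[, j]])
      col <- col + 1
    }
  }
  out
}
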
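# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: brute-force enumeration, O(n*m) scans
# and exact linear algebra on tiny problems.

# JC69 likelihood by full enumeration of internal-node states.
enum_jc69_ll <- function(tree, aln, rate = 1) {
  n <- length(tree$taxa)
  m <- 2L * n - 1L
  pmat <- function(t) {
    e <- exp(-4 * rate * t / 3)
    ps <- 0.25 + 0.75 * e
    pd <- 0.25 - 0.25 * e
    M <- matrix(pd, 4, 4)
    diag(M) <- ps
    M
  }
  codes <- match(aln$seqs, c("A", "C", "G", "T"))
  dim(codes) <- dim(aln$seqs)
  codes <- codes[match(tree$taxa, aln$taxa), , drop = FALSE]
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(1:4), n - 1)))
  for (s in seq_len(ncol(codes))) {
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      st <- c(codes[, s], grid[g, ])
      pr <- 0.25
      for (v in seq_len(m)) {
        p <- tree$parent[v]
        if (p > 0)
          pr <- pr * pmat(tree$heights[p] - tree$heights[v])[st[p], st[v]]
      }
      lik <- lik + pr
    }
    total <- total + log(lik)
  }
  total
}

# KS distance by an O(n*m) scan over every pooled point.
brute_ks <- function(a, b) {
  pts <- c(a, b)
  mx <- 0
  for (x in pts) {
    d <- abs(mean(a <= x) - mean(b <= x))
    if (d > mx) mx <- d
  }
  mx
}

# Transition matrix of one heated Metropolis chain on a discrete target
# with uniform proposals over the other states.
heated_transition_matrix <- function(log_target, beta) {
  k <- length(log_target)
  P <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    a <- exp(min(0, beta * (log_target[j] - log_target[i])))
    P[i, j] <- a / (k - 1)
  }
  diag(P) <- 1 - rowSums(P)
  P
}

stationary_of <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# AR(1) series with known autocorrelation time (1 + phi) / (1 - phi).
ar1_series <- function(n, phi) {
  x <- numeric(n)
  x[1] <- rnorm(1)
  eps <- rnorm(n - 1)
  for (i in 2:n) x[i] <- phi * x[i - 1] + eps[i - 1]
  x
}

# Two-taxon fixture tree with a single coalescence at `height`.
two_taxon_tree <- function(height) {
  new_tree(c("a", "b"), c(3L, 3L, 0L), matrix(c(1L, 2L), 1), c(0, 0, height))
}
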
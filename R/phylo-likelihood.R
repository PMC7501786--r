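#' Jukes-Cantor tree log-likelihood (Felsenstein pruning)
#'
#' Computes the log-likelihood of an alignment on a rooted ultrametric tree
#' under JC69 with equal base frequencies, by the pruning (sum-product)
#' algorithm over site patterns. Branch transition probabilities are
#' `p_same(t) = 1/4 + 3/4 e^{-4rt/3}` and `p_diff(t) = 1/4 - 1/4 e^{-4rt/3}`;
#' the root is closed with the stationary frequency 1/4. Partial likelihoods
#' are rescaled per node to keep the computation stable for long trees.
#'
#' @param tree An `mc3_tree`.
#' @param alignment An [new_alignment()] whose taxa match the tree's.
#' @param rate Substitution rate per unit height (> 0 unless the alignment
#'   is empty).
#' @return The log-likelihood; 0 for a zero-site alignment.
#' @export
jc69_log_likelihood <- function(tree, alignment, rate = 1) {
  stopifnot(inherits(tree, "mc3_tree"), inherits(alignment, "mc3_alignment"))
  if (!setequal(tree$taxa, alignment$taxa))
    stop("tree and alignment taxa differ", call. = FALSE)
  pat <- site_patterns(alignment)
  jc69_ll_patterns(tree, pat, rate)
}

# Pattern-level pruning; `pat` as from site_patterns(). Pattern taxa are
# matched to tree taxa by label.
jc69_ll_patterns <- function(tree, pat, rate = 1) {
  P <- length(pat$weights)
  if (P == 0L) return(0)
  stopifnot(rate > 0)
  n <- length(tree$taxa)
  ord <- match(tree$taxa, pat$taxa)
  states <- pat$states[ord, , drop = FALSE]  # rows now in tree tip order
  partial <- vector("list", 2L * n - 1L)
  jc_pmat <- function(t) {
    e <- exp(-4 * rate * t / 3)
    ps <- 0.25 + 0.75 * e
    pd <- 0.25 - 0.25 * e
    matrix(c(ps, pd, pd, pd,
             pd, ps, pd, pd,
             pd, pd, ps, pd,
             pd, pd, pd, ps), 4L, 4L)
  }
  # no per-node rescaling: per-site partials are bounded below by ~0.25^n,
  # far from underflow at testbed sizes (tens of taxa)
  hts <- tree$heights
  for (v in tree_postorder(tree)) {
    ch <- tree$children[v - n, ]
    c1 <- ch[1L]
    c2 <- ch[2L]
    P1 <- jc_pmat(hts[v] - hts[c1])
    P2 <- jc_pmat(hts[v] - hts[c2])
    a <- if (c1 <= n) P1[, states[c1, ], drop = FALSE] else P1 %*% partial[[c1]]
    b <- if (c2 <= n) P2[, states[c2, ], drop = FALSE] else P2 %*% partial[[c2]]
    partial[[v]] <- a * b
  }
  root <- tree_root(tree)
  site_lik <- colSums(partial[[root]]) * 0.25
  if (any(site_lik <= 0)) return(-Inf)
  sum(pat$weights * log(site_lik))
}

#' Kingman coalescent log-density of a genealogy
#'
#' Log probability density of an ultrametric tree under the constant-size
#' coalescent: for each inter-coalescent interval of duration \eqn{\tau}
#' with `k` extant lineages the density contributes
#' \eqn{-k(k-1)\tau / (2 N_e)}, and each of the `n-1` coalescent events
#' contributes \eqn{-\log N_e}.
#'
#' @param tree An `mc3_tree` (tips at height 0).
#' @param pop_size Population size `Ne` (> 0).
#' @return The log-density.
#' @export
coalescent_log_density <- function(tree, pop_size) {
  stopifnot(inherits(tree, "mc3_tree"))
  if (pop_size <= 0) return(-Inf)
  if (any(tree$heights[seq_along(tree$taxa)] != 0))
    stop("tree is not ultrametric (tips must sit at height 0)",
         call. = FALSE)
  n <- length(tree$taxa)
  ev <- sort(tree$heights[(n + 1L):(2L * n - 1L)])
  times <- c(0, ev)
  k <- seq(n, 2L)
  tau <- diff(times)
  sum(-k * (k - 1) * tau / (2 * pop_size)) - (n - 1L) * log(pop_size)
}
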
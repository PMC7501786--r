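#' Nucleotide alignment container
#'
#' @param taxa Character vector of taxon labels (unique).
#' @param seqs Character matrix (taxa x sites) over `A`, `C`, `G`, `T`.
#' @return An object of class `mc3_alignment`.
#' @export
new_alignment <- function(taxa, seqs) {
  seqs <- as.matrix(seqs)
  if (anyDuplicated(taxa)) stop("duplicate taxa", call. = FALSE)
  if (nrow(seqs) != length(taxa))
    stop("one sequence per taxon required", call. = FALSE)
  if (ncol(seqs) > 0L && !all(seqs %in% c("A", "C", "G", "T")))
    stop("sequences must be over A/C/G/T", call. = FALSE)
  rownames(seqs) <- taxa
  structure(list(taxa = taxa, seqs = seqs, n_sites = ncol(seqs)),
            class = "mc3_alignment")
}

#' @export
print.mc3_alignment <- function(x, ...) {
  cat(sprintf("Alignment: %d taxa x %d sites\n", length(x$taxa), x$n_sites))
  invisible(x)
}

NUC <- c("A", "C", "G", "T")

# Collapse an alignment to unique site patterns with weights; tip states
# coded 1..4. This is what makes repeated likelihood evaluation cheap.
site_patterns <- function(alignment) {
  if (alignment$n_sites == 0L)
    return(list(states = matrix(integer(0), length(alignment$taxa), 0L),
                weights = integer(0), taxa = alignment$taxa))
  codes <- matrix(match(alignment$seqs, NUC), nrow = length(alignment$taxa))
  key <- apply(codes, 2L, paste, collapse = ".")
  tab <- table(key)
  first <- match(names(tab), key)
  list(states = codes[, first, drop = FALSE],
       weights = as.integer(tab), taxa = alignment$taxa)
}

#' Simulate a Kingman coalescent genealogy
#'
#' Standard constant-population-size coalescent: with `k` extant lineages
#' the next coalescence occurs after an Exponential(k(k-1)/(2 Ne)) waiting
#' time between a uniformly chosen pair. Expected TMRCA is
#' `2 * Ne * (1 - 1/n)`.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param pop_size Population size `Ne` in coalescent units (> 0).
#' @param taxa Optional tip labels (default `t1..tn`).
#' @return An ultrametric [new_tree()] with tips at height 0.
#' @export
simulate_coalescent_tree <- function(n_taxa, pop_size = 1,
                                     taxa = paste0("t", seq_len(n_taxa))) {
  check_count(n_taxa, "n_taxa")
  if (n_taxa < 2L) stop("need at least 2 taxa", call. = FALSE)
  stopifnot(pop_size > 0)
  n <- as.integer(n_taxa)
  m <- 2L * n - 1L
  parent <- integer(m)
  children <- matrix(0L, n - 1L, 2L)
  heights <- numeric(m)
  active <- seq_len(n)
  t <- 0
  for (k in seq(n, 2L)) {
    t <- t + rexp(1L, rate = k * (k - 1L) / (2 * pop_size))
    pair <- sample(active, 2L)
    node <- 2L * n - k + 1L  # n+1, n+2, ... in coalescence order
    heights[node] <- t
    children[node - n, ] <- pair
    parent[pair] <- node
    active <- c(setdiff(active, pair), node)
  }
  new_tree(taxa, parent, children, heights)
}

#' Simulate sequences under Jukes-Cantor on a tree
#'
#' Root states are drawn iid uniform over the four nucleotides and evolved
#' down each branch with the JC69 transition probabilities
#' `p_same(t) = 1/4 + 3/4 exp(-4 r t / 3)`,
#' `p_diff(t) = 1/4 - 1/4 exp(-4 r t / 3)`.
#'
#' @param tree An `mc3_tree`.
#' @param n_sites Number of sites (>= 0).
#' @param rate Substitution rate `r` per unit height (default 1).
#' @return An [new_alignment()] with the tree's taxa.
#' @export
simulate_jc69_alignment <- function(tree, n_sites, rate = 1) {
  stopifnot(rate >= 0, n_sites >= 0)
  n <- length(tree$taxa)
  n_sites <- as.integer(n_sites)
  if (n_sites == 0L)
    return(new_alignment(tree$taxa,
                         matrix(character(0), n, 0L)))
  m <- 2L * n - 1L
  states <- matrix(0L, m, n_sites)
  root <- tree_root(tree)
  states[root, ] <- sample.int(4L, n_sites, replace = TRUE)
  preorder <- rev(tree_postorder(tree))  # parents before children
  for (v in preorder) {
    ch <- tree$children[v - n, ]
    for (c in ch) {
      t <- tree$heights[v] - tree$heights[c]
      p_same <- 0.25 + 0.75 * exp(-4 * rate * t / 3)
      keep <- runif(n_sites) < p_same
      s <- states[v, ]
      # a change moves to one of the three other states uniformly
      shift <- sample.int(3L, n_sites, replace = TRUE)
      s[!keep] <- ((s[!keep] - 1L + shift[!keep]) %% 4L) + 1L
      states[c, ] <- s
    }
  }
  new_alignment(tree$taxa,
                matrix(NUC[states[seq_len(n), ]], nrow = n))
}
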
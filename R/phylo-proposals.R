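# Standard tree moves for the coalescent testbed. Each low-level move
# returns `list(tree = ..., log_hastings = ...)` (or `list(state = ...)` for
# moves touching the full state) and `NULL` when the drawn move would
# violate tree geometry — the caller counts that as a rejected proposal.

#' Nearest-neighbour interchange (narrow exchange)
#'
#' Picks a random internal non-root node `c`, its sibling `s` and a random
#' child `a` of `c`, and swaps `s` and `a` between the two adjacent
#' branches. The move keeps all node heights fixed, is its own inverse, and
#' has a zero log-Hastings correction; it is invalid (rejection sentinel)
#' when the sibling sits at or above `c`.
#'
#' @param tree An `mc3_tree` with at least 4 taxa.
#' @return `list(tree, log_hastings = 0)` or `NULL`.
#' @export
propose_nni <- function(tree) {
  n <- length(tree$taxa)
  if (n < 4L) stop("NNI requires at least 4 taxa", call. = FALSE)
  root <- tree_root(tree)
  cand <- setdiff((n + 1L):(2L * n - 1L), root)
  cnode <- cand[sample.int(length(cand), 1L)]
  take_first <- runif(1) < 0.5
  p <- tree$parent[cnode]
  pch <- tree$children[p - n, ]
  s <- pch[pch != cnode]
  if (tree$heights[s] >= tree$heights[cnode]) return(NULL)
  cch <- tree$children[cnode - n, ]
  a <- if (take_first) cch[1L] else cch[2L]
  # swap a <-> s
  tree$children[p - n, ] <- ifelse(pch == s, a, pch)
  tree$children[cnode - n, ] <- ifelse(cch == a, s, cch)
  tree$parent[a] <- p
  tree$parent[s] <- cnode
  list(tree = tree, log_hastings = 0)
}

#' Uniform node-height move
#'
#' Redraws the height of a random internal non-root node uniformly between
#' the height of its highest child and its parent's height
#' (`log_hastings = 0`).
#'
#' @param tree An `mc3_tree` with at least 3 taxa.
#' @return `list(tree, log_hastings = 0)`.
#' @export
propose_uniform_node_height <- function(tree) {
  n <- length(tree$taxa)
  root <- tree_root(tree)
  cand <- setdiff((n + 1L):(2L * n - 1L), root)
  if (length(cand) == 0L) return(NULL)
  v <- cand[sample.int(length(cand), 1L)]
  lo <- max(tree$heights[tree$children[v - n, ]])
  hi <- tree$heights[tree$parent[v]]
  tree$heights[v] <- runif(1, lo, hi)
  list(tree = tree, log_hastings = 0)
}

#' Scale all internal node heights
#'
#' Multiplies every internal node height (root included) by a multiplier
#' drawn uniformly from `[sf, 1/sf]`. For a scale move acting on `k`
#' dimensions with a Uniform(sf, 1/sf) multiplier the combined
#' Hastings-Jacobian correction is `(k - 2) * log(m)`; here `k = n - 1`
#' internal heights. Height ordering is preserved, so the move is always
#' geometrically valid.
#'
#' @param tree An `mc3_tree`.
#' @param sf Scale factor bound in (0, 1) (default 0.75).
#' @return `list(tree, log_hastings)`.
#' @export
propose_height_scale <- function(tree, sf = 0.75) {
  stopifnot(sf > 0, sf < 1)
  n <- length(tree$taxa)
  m <- runif(1, sf, 1 / sf)
  idx <- (n + 1L):(2L * n - 1L)
  tree$heights[idx] <- tree$heights[idx] * m
  list(tree = tree, log_hastings = (n - 1L - 2L) * log(m))
}

#' Scale the population size
#'
#' One-dimensional scale move on `Ne` with a Uniform(sf, 1/sf) multiplier;
#' the Hastings-Jacobian correction for `k = 1` scaled dimension is
#' `-log(m)`.
#'
#' @param pop_size Current population size.
#' @param sf Scale factor bound in (0, 1) (default 0.75).
#' @return `list(pop_size, log_hastings)`.
#' @export
propose_popsize_scale <- function(pop_size, sf = 0.75) {
  stopifnot(sf > 0, sf < 1)
  m <- runif(1, sf, 1 / sf)
  list(pop_size = pop_size * m, log_hastings = -log(m))
}

# -- engine-facing wrappers on the full PhyloState ---------------------------

#' @rdname propose_nni
#' @param weight Selection weight for the engine's operator mix.
#' @export
proposal_nni <- function(weight = 2) {
  mc3_proposal(function(state) {
    mv <- propose_nni(state$tree)
    if (is.null(mv)) return(NULL)
    state$tree <- mv$tree
    list(state = state, log_hastings = mv$log_hastings)
  }, weight = weight, name = "nni")
}

#' @rdname propose_uniform_node_height
#' @param weight Selection weight for the engine's operator mix.
#' @export
proposal_node_height <- function(weight = 2) {
  mc3_proposal(function(state) {
    mv <- propose_uniform_node_height(state$tree)
    if (is.null(mv)) return(NULL)
    state$tree <- mv$tree
    list(state = state, log_hastings = mv$log_hastings)
  }, weight = weight, name = "node_height")
}

#' @rdname propose_height_scale
#' @param weight Selection weight for the engine's operator mix.
#' @export
proposal_tree_scale <- function(sf = 0.75, weight = 1) {
  force(sf)
  mc3_proposal(function(state) {
    mv <- propose_height_scale(state$tree, sf)
    state$tree <- mv$tree
    list(state = state, log_hastings = mv$log_hastings)
  }, weight = weight, name = "tree_scale", scale = sf)
}

#' @rdname propose_popsize_scale
#' @param weight Selection weight for the engine's operator mix.
#' @export
proposal_popsize <- function(sf = 0.75, weight = 1) {
  force(sf)
  mc3_proposal(function(state) {
    mv <- propose_popsize_scale(state$pop_size, sf)
    state$pop_size <- mv$pop_size
    list(state = state, log_hastings = mv$log_hastings)
  }, weight = weight, name = "popsize_scale", scale = sf)
}
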
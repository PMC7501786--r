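# Rooted ultrametric trees for the coalescent testbed. Nodes are indexed
# 1..(2n-1): tips 1..n (in `taxa` order, at height 0), internal nodes
# n+1..2n-1. `children[k, ]` holds the two children of internal node n+k;
# `parent` is 0 at the root. Heights strictly increase from child to parent,
# so sorting internal nodes by height gives a valid postorder.

#' Construct a rooted ultrametric tree
#'
#' @param taxa Character vector of tip labels (unique).
#' @param parent Integer vector of length `2n-1`; `parent[v]` is the parent
#'   node of `v`, 0 for the root.
#' @param children Integer matrix `(n-1) x 2`; row `k` holds the children of
#'   internal node `n + k`.
#' @param heights Numeric vector of node heights (tips at 0, parents
#'   strictly above children).
#' @return An object of class `mc3_tree`.
#' @export
new_tree <- function(taxa, parent, children, heights) {
  tr <- structure(list(taxa = taxa, parent = as.integer(parent),
                       children = matrix(as.integer(children), ncol = 2L),
                       heights = as.numeric(heights)),
                  class = "mc3_tree")
  validate_tree(tr)
  tr
}

#' Validate tree invariants
#'
#' Checks binary rooted topology, tip heights of zero, strict child-parent
#' height ordering and parent/children consistency.
#'
#' @param tree An `mc3_tree`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_tree <- function(tree) {
  n <- length(tree$taxa)
  if (anyDuplicated(tree$taxa)) stop("duplicate taxa", call. = FALSE)
  m <- 2L * n - 1L
  stopifnot(length(tree$parent) == m, nrow(tree$children) == n - 1L,
            length(tree$heights) == m)
  if (sum(tree$parent == 0L) != 1L)
    stop("tree must have exactly one root", call. = FALSE)
  root <- which(tree$parent == 0L)
  if (n > 1L && root <= n) stop("root must be an internal node", call. = FALSE)
  if (any(tree$heights[seq_len(n)] != 0))
    stop("tips must be at height 0", call. = FALSE)
  for (k in seq_len(n - 1L)) {
    node <- n + k
    ch <- tree$children[k, ]
    if (any(tree$parent[ch] != node))
      stop("parent/children tables disagree at node ", node, call. = FALSE)
    if (any(tree$heights[ch] >= tree$heights[node]))
      stop("internal node ", node, " is not above its children",
           call. = FALSE)
  }
  invisible(TRUE)
}

tree_root <- function(tree) which(tree$parent == 0L)

#' Root height (time to most recent common ancestor)
#' @param tree An `mc3_tree`.
#' @return Numeric height of the root.
#' @export
tree_height <- function(tree) tree$heights[tree_root(tree)]

#' Sum of branch lengths
#' @param tree An `mc3_tree`.
#' @return Total tree length.
#' @export
tree_length <- function(tree) {
  nz <- tree$parent != 0L
  sum(tree$heights[tree$parent[nz]] - tree$heights[nz])
}

# Internal nodes sorted by height: children always precede parents.
tree_postorder <- function(tree) {
  n <- length(tree$taxa)
  internal <- (n + 1L):(2L * n - 1L)
  internal[order(tree$heights[internal])]
}

#' Descendant tip sets of every internal node
#'
#' @param tree An `mc3_tree`.
#' @return List mapping each internal node (names `"n+1"`, ...) to the sorted
#'   tip labels below it; the root maps to all taxa.
#' @export
tree_clades <- function(tree) {
  n <- length(tree$taxa)
  below <- vector("list", 2L * n - 1L)
  for (i in seq_len(n)) below[[i]] <- tree$taxa[i]
  po <- tree_postorder(tree)
  for (v in po) {
    ch <- tree$children[v - n, ]
    below[[v]] <- sort(c(below[[ch[1L]]], below[[ch[2L]]]))
  }
  res <- below[po]
  names(res) <- po
  res
}

# Canonical topology key (clade strings joined), used for topology counting.
topology_key <- function(tree) {
  cl <- vapply(tree_clades(tree), paste, "", collapse = ",")
  paste(sort(cl), collapse = ";")
}

#' Newick serialization
#'
#' Writes the tree as a rooted Newick string with branch lengths derived
#' from node heights, at 17 significant digits (heights are the primary
#' representation; branch lengths are derived).
#'
#' @param tree An `mc3_tree`.
#' @param digits Significant digits for branch lengths (default 17).
#' @return A single Newick string, terminated by `;`.
#' @export
write_newick <- function(tree, digits = 17L) {
  n <- length(tree$taxa)
  fmt <- paste0("%.", digits, "g")
  rec <- function(v) {
    lab <- if (v <= n) tree$taxa[v] else {
      ch <- tree$children[v - n, ]
      paste0("(", rec(ch[1L]), ",", rec(ch[2L]), ")")
    }
    p <- tree$parent[v]
    if (p == 0L) lab
    else paste0(lab, ":", sprintf(fmt, tree$heights[p] - tree$heights[v]))
  }
  paste0(rec(tree_root(tree)), ";")
}

#' Convert to an \pkg{ape} `phylo` object
#'
#' @param tree An `mc3_tree`.
#' @return An object of class `phylo` (rooted, with edge lengths).
#' @export
as_phylo <- function(tree) {
  ape::read.tree(text = write_newick(tree))
}

#' Convert an \pkg{ape} `phylo` object to an `mc3_tree`
#'
#' The input must be rooted, binary, with edge lengths, and ultrametric to
#' within `tol` (tip heights are snapped to zero).
#'
#' @param phy A `phylo` object.
#' @param tol Ultrametricity tolerance on tip heights (default 1e-6 relative
#'   to tree height).
#' @return An `mc3_tree`.
#' @export
from_phylo <- function(phy, tol = 1e-6) {
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  if (!ape::is.binary(phy)) stop("tree must be binary", call. = FALSE)
  if (is.null(phy$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  n <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)  # distance from root
  h <- max(depth) - depth
  if (any(abs(h[seq_len(n)]) > tol * max(h)))
    stop("tree is not ultrametric", call. = FALSE)
  h[seq_len(n)] <- 0
  # ape numbering: tips 1..n, root n+1. Ours: internal nodes ordered freely;
  # keep ape's internal numbering, which is already n+1..2n-1.
  parent <- integer(2L * n - 1L)
  children <- matrix(0L, n - 1L, 2L)
  fill <- integer(n - 1L)
  for (ei in seq_len(nrow(phy$edge))) {
    a <- phy$edge[ei, 1L]
    b <- phy$edge[ei, 2L]
    parent[b] <- a
    k <- a - n
    fill[k] <- fill[k] + 1L
    children[k, fill[k]] <- b
  }
  new_tree(phy$tip.label, parent, children, h)
}

#' @export
print.mc3_tree <- function(x, ...) {
  cat(sprintf("Rooted ultrametric tree, %d tips, height %.4g\n",
              length(x$taxa), tree_height(x)))
  cat(" ", write_newick(x, digits = 4L), "\n")
  invisible(x)
}

serialize_tree <- function(tree) {
  list(taxa = tree$taxa, parent = tree$parent,
       children = as.integer(tree$children),
       heights = fmt17(tree$heights))
}

deserialize_tree <- function(obj) {
  new_tree(unlist(obj$taxa), as.integer(unlist(obj$parent)),
           matrix(as.integer(unlist(obj$children)), ncol = 2L),
           as.numeric(unlist(obj$heights)))
}
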
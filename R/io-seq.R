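# FASTA, Newick and NEXUS input/output. Reading goes through ape (which
# handles line wrapping, quoting and translate blocks); writing of tree
# logs uses a plain translate-block NEXUS layout readable by ape and by the
# usual tree-set tools.

#' Read a FASTA alignment
#'
#' @param path FASTA file (wrapped or unwrapped lines).
#' @return An [new_alignment()].
#' @export
read_fasta <- function(path) {
  bin <- ape::read.FASTA(path)
  if (length(bin) == 0L) stop("no sequences in '", path, "'", call. = FALSE)
  chars <- lapply(as.character(bin), toupper)
  lens <- lengths(chars)
  if (length(unique(lens)) != 1L)
    stop("sequences in '", path, "' have unequal lengths", call. = FALSE)
  new_alignment(names(bin), do.call(rbind, chars))
}

#' Write a FASTA alignment
#'
#' @param alignment An [new_alignment()].
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(alignment, path, width = 70L) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(alignment$taxa)) {
    writeLines(paste0(">", alignment$taxa[i]), con)
    s <- paste(alignment$seqs[i, ], collapse = "")
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path File with one Newick tree, or a Newick string when
#'   `text = TRUE`.
#' @param text Interpret `path` as the Newick string itself.
#' @return An `mc3_tree` (the tree must be rooted, binary, ultrametric).
#' @export
read_newick <- function(path, text = FALSE) {
  phy <- if (text) ape::read.tree(text = path) else ape::read.tree(path)
  if (is.null(phy)) stop("could not parse Newick input", call. = FALSE)
  from_phylo(phy)
}

#' Write a Newick tree file
#'
#' @param tree An `mc3_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick_file <- function(tree, path) {
  writeLines(write_newick(tree), path)
  invisible(path)
}

#' Write a NEXUS tree log
#'
#' One tree per logged sample, with a translate block mapping integer
#' indices to taxon labels.
#'
#' @param trees List of `mc3_tree` objects over the same taxa.
#' @param path Output path.
#' @param iterations Optional iteration numbers used in the tree names
#'   (`STATE_<iteration>`); defaults to 0, 1, 2, ...
#' @return `path`, invisibly.
#' @export
write_tree_log <- function(trees, path, iterations = NULL) {
  stopifnot(length(trees) >= 1L)
  taxa <- trees[[1L]]$taxa
  if (is.null(iterations)) iterations <- seq_along(trees) - 1L
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("Begin taxa;", con)
  writeLines(sprintf("\tDimensions ntax=%d;", length(taxa)), con)
  writeLines("\tTaxlabels", con)
  writeLines(paste0("\t\t", taxa), con)
  writeLines("\t\t;", con)
  writeLines("End;", con)
  writeLines("Begin trees;", con)
  writeLines("\tTranslate", con)
  writeLines(paste0("\t\t", seq_along(taxa), " ", taxa,
                    c(rep(",", length(taxa) - 1L), "")), con)
  writeLines("\t\t;", con)
  for (i in seq_along(trees)) {
    tr <- trees[[i]]
    if (!identical(tr$taxa, taxa))
      stop("trees in a log must share one taxon order", call. = FALSE)
    tr$taxa <- as.character(match(tr$taxa, taxa))
    writeLines(sprintf("tree STATE_%d = [&R] %s",
                       as.integer(iterations[i]), write_newick(tr)), con)
  }
  writeLines("End;", con)
  invisible(path)
}

#' Read a NEXUS tree log
#'
#' @param path NEXUS file with a trees block (translate block supported).
#' @return List of `mc3_tree` objects.
#' @export
read_tree_log <- function(path) {
  phys <- ape::read.nexus(path)
  if (inherits(phys, "phylo")) phys <- list(phys)
  lapply(phys, from_phylo)
}
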
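#' Bayesian phylogenetic target: JC69 likelihood + coalescent prior
#'
#' Builds the testbed posterior over `(tree, Ne)`: a Jukes-Cantor
#' tree likelihood (strict clock, rate fixed; heights are therefore in
#' expected substitutions per site when `rate = 1`) combined with a
#' constant-size Kingman coalescent prior on the genealogy and, unless the
#' population size is fixed, a log-normal(0, 1) prior on `Ne`. With a `NULL`
#' or zero-site alignment the likelihood is identically zero and the target
#' samples the prior — the standard way to validate sampler machinery.
#'
#' @param alignment An [new_alignment()], or `NULL` for a prior-only target.
#' @param n_taxa Number of taxa (required when `alignment` is `NULL`).
#' @param taxa Optional taxon labels for prior-only targets.
#' @param rate Fixed substitution rate (default 1).
#' @param pop_size Fix `Ne` at this value instead of estimating it
#'   (default `NULL`: estimate under the log-normal(0, 1) prior).
#' @param ne_meanlog,ne_sdlog Log-normal prior parameters for `Ne`.
#' @return An `mc3_target` over states `list(tree, pop_size)`, with default
#'   proposals (NNI when `n_taxa >= 4`, uniform node height, tree-height
#'   scale, and an `Ne` scale when `Ne` is estimated).
#' @examples
#' tr <- simulate_coalescent_tree(5, 1)
#' aln <- simulate_jc69_alignment(tr, 100)
#' tgt <- target_phylo(aln)
#' @export
target_phylo <- function(alignment = NULL, n_taxa = NULL, taxa = NULL,
                         rate = 1, pop_size = NULL,
                         ne_meanlog = 0, ne_sdlog = 1) {
  prior_only <- is.null(alignment) || alignment$n_sites == 0L
  if (is.null(alignment)) {
    if (is.null(n_taxa)) stop("give `alignment` or `n_taxa`", call. = FALSE)
    if (is.null(taxa)) taxa <- paste0("t", seq_len(n_taxa))
  } else {
    taxa <- alignment$taxa
    n_taxa <- length(taxa)
  }
  estimate_ne <- is.null(pop_size)
  pat <- if (prior_only) NULL else site_patterns(alignment)
  log_likelihood <- if (prior_only) function(state) 0
    else function(state) jc69_ll_patterns(state$tree, pat, rate)
  log_prior <- function(state) {
    if (state$pop_size <= 0) return(-Inf)
    lp <- coalescent_log_density(state$tree, state$pop_size)
    if (estimate_ne)
      lp <- lp + stats::dlnorm(state$pop_size, ne_meanlog, ne_sdlog,
                               log = TRUE)
    lp
  }
  init <- function() {
    ne0 <- if (estimate_ne) stats::rlnorm(1, ne_meanlog, ne_sdlog)
           else pop_size
    list(tree = simulate_coalescent_tree(n_taxa, ne0, taxa),
         pop_size = ne0)
  }
  props <- list(proposal_node_height(weight = 2),
                proposal_tree_scale(weight = 1))
  if (n_taxa >= 4L) props <- c(list(proposal_nni(weight = 2)), props)
  if (estimate_ne) props <- c(props, list(proposal_popsize(weight = 1)))
  mc3_target(
    log_likelihood = log_likelihood,
    log_prior = log_prior,
    init = init,
    params = function(state) c(tree_height = tree_height(state$tree),
                               tree_length = tree_length(state$tree),
                               pop_size = state$pop_size),
    default_proposals = props,
    serialize = function(state)
      list(tree = serialize_tree(state$tree),
           pop_size = fmt17(state$pop_size)),
    deserialize = function(obj)
      list(tree = deserialize_tree(obj$tree),
           pop_size = as.numeric(obj$pop_size)),
    get_tree = function(state) state$tree,
    label = sprintf("phylo%d%s", n_taxa, if (prior_only) "-prior" else "")
  )
}
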
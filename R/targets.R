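#' Define a target model for the sampler
#'
#' A target bundles the log-likelihood and log-prior of a model, an
#' initializer, and a handful of optional hooks used by the engine. Targets
#' are deliberately lightweight lists of closures so that any model — the
#' built-in toy targets, the phylogenetic testbed, or a user's own — plugs
#' into the same tempering machinery.
#'
#' @param log_likelihood Function `state -> numeric(1)`, the log P(D|x).
#' @param log_prior Function `state -> numeric(1)`, the log P(x). May return
#'   `-Inf` for states outside the support.
#' @param init Function `() -> state`, drawing or constructing an initial
#'   state (called under the chain's own RNG stream).
#' @param params Function `state -> named numeric`, the scalar summaries
#'   written to the trace log.
#' @param default_proposals Optional list of [mc3_proposal()] objects used
#'   when `run_mc3()` is called without an explicit proposal set.
#' @param serialize,deserialize Optional functions converting a state to and
#'   from a JSON-representable list; used by checkpointing. Default to the
#'   identity (adequate for plain numeric states).
#' @param kernel Internal: descriptor `list(id, pars)` marking targets whose
#'   within-chain updates can run in compiled code.
#' @param get_tree Optional function `state -> tree` for targets whose state
#'   contains a genealogy; enables tree logging.
#' @param label Short name used in logs and manifests.
#' @return An object of class `mc3_target`.
#' @export
mc3_target <- function(log_likelihood, log_prior, init, params,
                       default_proposals = NULL,
                       serialize = NULL, deserialize = NULL,
                       kernel = NULL, get_tree = NULL, label = "custom") {
  stopifnot(is.function(log_likelihood), is.function(log_prior),
            is.function(init), is.function(params))
  # default (de)serializers assume a plain numeric state; 17 significant
  # digits so checkpointed states resume bit-for-bit
  if (is.null(serialize)) serialize <- function(state) fmt17(state)
  if (is.null(deserialize))
    deserialize <- function(obj) as.numeric(unlist(obj))
  structure(
    list(log_likelihood = log_likelihood, log_prior = log_prior,
         init = init, params = params,
         default_proposals = default_proposals,
         serialize = serialize, deserialize = deserialize,
         kernel = kernel, get_tree = get_tree, label = label),
    class = "mc3_target"
  )
}

#' Built-in multivariate normal toy target
#'
#' An isotropic zero-mean normal in `dim` dimensions, with the whole log
#' density treated as the "likelihood" and a flat prior. The default
#' dimension of 50 is chosen so that the log-posterior fluctuations of the
#' target (standard deviation \eqn{\sqrt{d/2}} at the cold chain, inflated by
#' \eqn{1/\beta} on heated chains) resemble those of a moderately sized real
#' posterior rather than a one-dimensional caricature; with only a handful of
#' dimensions the swap acceptance stays near 1 until the ladder is implausibly
#' hot, which is not the regime the adaptive spacing rule operates in.
#'
#' @param dim Dimensionality (default 400).
#' @param sd Standard deviation of each coordinate (default 1).
#' @param prop_halfwidth Half-width of the default uniform-window proposal
#'   (default `sqrt(3) * 2.4 * sd / sqrt(dim)`: the classic
#'   `2.4 sd / sqrt(d)` random-walk scaling, converted to the uniform window
#'   of equal variance).
#' @return An `mc3_target` whose within-chain updates run in compiled code.
#' @examples
#' t <- target_normal(dim = 2)
#' t$log_likelihood(c(0, 0))
#' @export
target_normal <- function(dim = 400, sd = 1,
                          prop_halfwidth = sqrt(3) * 2.4 * sd / sqrt(dim)) {
  check_count(dim, "dim")
  pars <- c(dim, sd)
  mc3_target(
    log_likelihood = function(state) builtin_logdens_cpp(state, 1L, pars),
    log_prior = function(state) 0,
    init = function() rnorm(dim, 0, sd),
    params = function(state) c(x1 = state[[1]]),
    default_proposals = list(proposal_uniform_walk(prop_halfwidth)),
    kernel = list(id = 1L, pars = pars),
    label = sprintf("normal%d", dim)
  )
}

#' Built-in multi-modal "island" toy target
#'
#' A one-dimensional mixture of `n_islands` equally weighted narrow normal
#' modes (standard deviation `sd`, default 0.05) at unit spacing, with the
#' log-density valley between the outermost modes floored exactly
#' `barrier_depth` below the mode peaks. Each mode carries mass
#' `1/n_islands` (up to a negligible contribution from the floored valley,
#' of order `exp(-barrier_depth)`). This emulates the "tree island"
#' pathology of hard phylogenetic posteriors: regions of high posterior
#' probability separated by intermediates so unfavourable that an unheated
#' chain essentially never crosses.
#'
#' @param n_islands Number of modes (>= 1); mode centres sit at 1..n_islands.
#' @param barrier_depth Depth of the inter-mode log-density valley below the
#'   peaks (default 25).
#' @param sd Mode standard deviation (default 0.05).
#' @param prop_halfwidth Half-width of the default uniform-window proposal
#'   (default 0.35, i.e. step standard deviation 0.2: small relative to the
#'   unit mode spacing, so an unheated chain is a within-mode sampler).
#' @param start_mode Optional mode index to initialize in (default: mode 1).
#' @return An `mc3_target` whose within-chain updates run in compiled code.
#' @seealso [mode_occupancy()]
#' @export
make_island_target <- function(n_islands, barrier_depth = 25, sd = 0.05,
                               prop_halfwidth = 0.35, start_mode = 1) {
  check_count(n_islands, "n_islands")
  check_nonneg(barrier_depth, "barrier_depth")
  stopifnot(start_mode >= 1, start_mode <= n_islands)
  pars <- c(n_islands, sd, barrier_depth)
  mc3_target(
    log_likelihood = function(state) builtin_logdens_cpp(state, 2L, pars),
    log_prior = function(state) 0,
    init = function() start_mode + rnorm(1, 0, sd),
    params = function(state) c(x = state[[1]]),
    default_proposals = list(proposal_uniform_walk(prop_halfwidth)),
    kernel = list(id = 2L, pars = pars),
    label = sprintf("island%d", n_islands)
  )
}

#' Assign island-target samples to their nearest mode
#'
#' @param x Numeric vector of sampled positions.
#' @param n_islands Number of modes of the target (centres at 1..n_islands).
#' @return Vector of occupancy fractions per mode (sums to 1).
#' @export
mode_occupancy <- function(x, n_islands) {
  m <- pmin(pmax(round(x), 1), n_islands)
  tabulate(m, nbins = n_islands) / length(x)
}

log_posterior_of <- function(target, state) {
  ll <- target$log_likelihood(state)
  lp <- target$log_prior(state)
  list(log_likelihood = ll, log_prior = lp, log_posterior = ll + lp)
}
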
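#' Define a proposal (operator) for the sampler
#'
#' A proposal wraps a `propose` closure together with a selection weight and
#' an optional tunable scale. `propose(state)` must return
#' `list(state = <new state>, log_hastings = <numeric>)`, or `NULL` as a
#' rejection sentinel when the move cannot produce a valid state (such moves
#' still count as proposed and rejected).
#'
#' Proposals whose `scale` is tunable can be auto-optimised by the engine
#' (off by default): the engine then rebuilds the proposal with
#' `with_scale()` as its acceptance-rate window drifts from the optimum.
#' Tuning state travels with the temperature rank, not the chain, so an
#' operator stays optimised for the temperature it serves.
#'
#' @param propose Function `state -> list(state, log_hastings)` or `NULL`.
#' @param weight Relative selection weight (> 0).
#' @param name Operator name (used in reports).
#' @param scale Optional tunable scale parameter.
#' @param with_scale Optional function `scale -> mc3_proposal` rebuilding the
#'   proposal at a new scale; its presence marks the proposal as tunable.
#' @return An object of class `mc3_proposal`.
#' @export
mc3_proposal <- function(propose, weight = 1, name = "proposal",
                         scale = NULL, with_scale = NULL) {
  stopifnot(is.function(propose), weight > 0)
  structure(list(propose = propose, weight = weight, name = name,
                 scale = scale, with_scale = with_scale),
            class = "mc3_proposal")
}

#' Gaussian random-walk proposal
#'
#' Symmetric proposal adding `rnorm(d, 0, sd)` to a numeric state
#' (`log_hastings = 0`).
#'
#' @param sd Step standard deviation.
#' @param weight Relative selection weight.
#' @return An `mc3_proposal`.
#' @export
proposal_rw <- function(sd = 0.5, weight = 1) {
  force(sd)
  mc3_proposal(
    propose = function(state)
      list(state = state + rnorm(length(state), 0, sd), log_hastings = 0),
    weight = weight, name = "random_walk", scale = sd,
    with_scale = function(s) proposal_rw(s, weight)
  )
}

#' Uniform-window random-walk proposal
#'
#' Symmetric proposal adding an independent Uniform(-halfwidth, halfwidth)
#' perturbation to every coordinate (`log_hastings = 0`). Statistically
#' comparable to a Gaussian walk of matched variance
#' (`sd = halfwidth / sqrt(3)`) while needing a single uniform deviate per
#' coordinate; this is the default operator of the built-in toy targets,
#' whose within-chain updates run in compiled code.
#'
#' @param halfwidth Window half-width.
#' @param weight Relative selection weight.
#' @return An `mc3_proposal`.
#' @export
proposal_uniform_walk <- function(halfwidth = 0.5, weight = 1) {
  force(halfwidth)
  mc3_proposal(
    propose = function(state)
      list(state = state + runif(length(state), -halfwidth, halfwidth),
           log_hastings = 0),
    weight = weight, name = "uniform_walk", scale = halfwidth,
    with_scale = function(s) proposal_uniform_walk(s, weight)
  )
}

# Can this (target, proposals) pair run in the compiled kernel?
use_compiled_kernel <- function(target, proposals) {
  !is.null(target$kernel) && length(proposals) == 1L &&
    identical(proposals[[1L]]$name, "uniform_walk")
}

# Advance one chain by `nsteps` within-chain Metropolis-Hastings steps at
# temperature `beta`. `ev` is the cached evaluation
# list(log_likelihood, log_prior). Must be called under the chain's RNG
# stream. Returns updated state/evaluation and the number of accepted moves.
advance_chain <- function(target, proposals, state, ev, beta, nsteps) {
  if (nsteps == 0L)
    return(list(state = state, ev = ev, n_accept = 0L))
  if (use_compiled_kernel(target, proposals)) {
    # temperature-aware step size: a chain at temperature beta samples a
    # target inflated by 1/sqrt(beta), so its random-walk step is inflated
    # the same way to keep mixing comparable across the ladder
    res <- advance_builtin_cpp(as.numeric(state), ev$log_likelihood, beta,
                               as.integer(nsteps),
                               proposals[[1L]]$scale / sqrt(beta),
                               target$kernel$id, target$kernel$pars)
    return(list(state = res$state,
                ev = list(log_likelihood = res$log_likelihood,
                          log_prior = 0),
                n_accept = res$n_accept))
  }
  np <- length(proposals)
  if (np > 1L) {
    w <- vapply(proposals, function(p) p$weight, numeric(1))
    w <- w / sum(w)
  }
  ll <- ev$log_likelihood
  lp <- ev$log_prior
  n_accept <- 0L
  for (s in seq_len(nsteps)) {
    k <- if (np == 1L) 1L else sample.int(np, 1L, prob = w)
    pr <- proposals[[k]]$propose(state)
    u <- runif(1)  # one decision draw per step, proposed or not
    if (is.null(pr)) next
    ll2 <- target$log_likelihood(pr$state)
    lp2 <- target$log_prior(pr$state)
    la <- heated_log_accept(ll2 + lp2, ll + lp, pr$log_hastings, beta)
    if (la >= 0 || log(u) < la) {
      state <- pr$state
      ll <- ll2
      lp <- lp2
      n_accept <- n_accept + 1L
    }
  }
  list(state = state,
       ev = list(log_likelihood = ll, log_prior = lp),
       n_accept = n_accept)
}
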
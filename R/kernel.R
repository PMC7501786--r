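#' Metropolis-Hastings log acceptance probability
#'
#' Computes the log of the usual Metropolis-Hastings acceptance probability
#' \eqn{\min(1, \frac{\pi(x')}{\pi(x)} \frac{g(x|x')}{g(x'|x)})} in log
#' space. All kernels in this package work in log space: posterior ratios of
#' realistic targets (e.g. phylogenetic likelihoods over thousands of sites)
#' overflow long before the ratio itself is informative.
#'
#' @param log_post_new Log posterior of the proposed state.
#' @param log_post_old Log posterior of the current state; must be finite
#'   (chains must be initialized in the support of the target).
#' @param log_hastings Log Hastings correction
#'   \eqn{\log g(x|x') - \log g(x'|x)}; 0 for symmetric proposals.
#' @return Log acceptance probability, always <= 0. A proposal with
#'   `log_post_new = -Inf` yields `-Inf` (certain rejection).
#' @examples
#' mh_log_accept(-12, -10, 0)  # exp(-2) acceptance
#' @export
mh_log_accept <- function(log_post_new, log_post_old, log_hastings = 0) {
  if (!is.finite(log_post_old))
    stop("current state has non-finite log posterior; ",
         "chains must start in the support of the target", call. = FALSE)
  min(0, (log_post_new - log_post_old) + log_hastings)
}

#' Heated (tempered) log acceptance probability
#'
#' Acceptance rule of a heated chain: the posterior ratio is raised to the
#' chain's temperature \eqn{\beta \in (0, 1]} before comparison, which
#' flattens the target and lets hot chains cross probability valleys. The
#' Hastings correction is not heated. Note that the *whole* posterior
#' (likelihood and prior together) is tempered; an option to heat only the
#' likelihood is deliberately not provided.
#'
#' @inheritParams mh_log_accept
#' @param beta Temperature scaler in (0, 1]; `beta = 1` recovers
#'   [mh_log_accept()].
#' @return Log acceptance probability, always <= 0.
#' @examples
#' heated_log_accept(-12, -10, 0, beta = 0.5)  # exp(-1) acceptance
#' @export
heated_log_accept <- function(log_post_new, log_post_old, log_hastings = 0,
                              beta = 1) {
  if (!is.finite(log_post_old))
    stop("current state has non-finite log posterior; ",
         "chains must start in the support of the target", call. = FALSE)
  if (beta <= 0 || beta > 1)
    stop("`beta` must be in (0, 1]", call. = FALSE)
  d <- log_post_new - log_post_old
  # beta * -Inf is still -Inf: out-of-support proposals are rejected
  min(0, beta * d + log_hastings)
}

#' Log acceptance probability of an inter-chain swap
#'
#' Acceptance rule for exchanging the states of two coupled chains running at
#' temperatures `beta_i` and `beta_j`:
#' \deqn{R_{ij} = \min\left(1,
#'   \frac{P(x_i|D)^{\beta_j} P(x_j|D)^{\beta_i}}
#'        {P(x_i|D)^{\beta_i} P(x_j|D)^{\beta_j}}\right)}
#' which in log space is
#' \eqn{\min(0, (\beta_i - \beta_j)(\log P(x_j|D) - \log P(x_i|D)))}. The
#' expression is symmetric in the labelling of the pair, so either chain may
#' be passed first. The swap is accepted when `log(runif(1))` is below the
#' returned value.
#'
#' @param log_post_i,log_post_j Unheated log posteriors of the two chains'
#'   current states.
#' @param beta_i,beta_j Temperatures of the two chains, each in (0, 1].
#' @return Log acceptance probability, always <= 0. Any `-Inf` log posterior
#'   yields `-Inf` unless the temperatures are equal.
#' @examples
#' swap_log_accept(-10, -8, 1.0, 0.8)  # hot chain holds the better state: 0
#' @export
swap_log_accept <- function(log_post_i, log_post_j, beta_i, beta_j) {
  if (any(c(beta_i, beta_j) <= 0) || any(c(beta_i, beta_j) > 1))
    stop("temperatures must be in (0, 1]", call. = FALSE)
  db <- beta_i - beta_j
  if (db == 0) return(0)
  if (!is.finite(log_post_i) || !is.finite(log_post_j)) return(-Inf)
  min(0, db * (log_post_j - log_post_i))
}
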
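#' Spacing update toward the target swap acceptance
#'
#' One step of the adaptive tuning rule for the ladder spacing:
#' \deqn{\Delta t_{new} = \max\left(0,\; \Delta t_{current} +
#'   \frac{p_{global} - p_{target}}{\#exchanges}\right)}
#' where `#exchanges` is the total number of *proposed* exchanges since the
#' start of the run. The signed step is clamped to `max_step` (default 0.001)
#' before the floor at zero is applied, so a single update can never move the
#' spacing by more than `max_step`; this protects against over-adaptation
#' early in the run when `#exchanges` is small and heated chains lag behind
#' their new equilibrium. Because the step shrinks as O(1/#exchanges), the
#' spacing becomes approximately constant late in the run, which is what
#' makes the (non-Markovian) adaptive sampler ergodic.
#'
#' The update is self-correcting: realized acceptance above the target grows
#' the spacing (hotter ladder, future swaps accepted less often) and vice
#' versa. At the absorbing-looking boundary `spacing = 0` all chains are cold
#' and every swap is accepted, so `p_global` is pushed to 1 and the next
#' gated update moves the spacing back up.
#'
#' @param current Current spacing (>= 0).
#' @param p_global Realized acceptance fraction over all proposed exchanges
#'   since the start of the run, in `[0, 1]`.
#' @param p_target Target acceptance probability in (0, 1); default 0.234.
#' @param n_exchanges Total number of proposed exchanges so far (>= 1).
#' @param max_step Largest allowed change per update (default 0.001).
#' @return The new spacing: non-negative, and within `max_step` of `current`.
#' @examples
#' update_spacing(0.1, 0.5, 0.234, 1000)  # small unclamped step up
#' update_spacing(0.1, 0.5, 0.234, 100)   # clamped to +0.001
#' @export
update_spacing <- function(current, p_global, p_target = 0.234,
                           n_exchanges, max_step = 0.001) {
  check_nonneg(current, "current")
  check_count(n_exchanges, "n_exchanges")
  stopifnot(p_global >= 0, p_global <= 1, p_target > 0, p_target < 1)
  s <- (p_global - p_target) / n_exchanges
  s <- sign(s) * min(abs(s), max_step)
  max(0, current + s)
}

#' Swap-acceptance bookkeeping for adaptive tuning
#'
#' Creates the state object that tracks, across a run, the global
#' swap-acceptance fraction (all proposed exchanges since the start) and a
#' local one (the last `local_window` proposed exchanges). Both drive the
#' locally aware gate of [adaptation_gate()].
#'
#' @param p_target Target acceptance probability in (0, 1).
#' @param burn_in Number of initial proposed exchanges during which the
#'   spacing is never updated (default 100).
#' @param local_window Number of most recent outcomes over which the local
#'   acceptance is computed (default 100).
#' @param max_step Clamp on a single spacing update (default 0.001).
#' @return An object of class `adaptation_state`.
#' @export
adaptation_state <- function(p_target = 0.234, burn_in = 100L,
                             local_window = 100L, max_step = 0.001) {
  stopifnot(p_target > 0, p_target < 1)
  check_count(burn_in, "burn_in")
  check_count(local_window, "local_window")
  structure(
    list(p_target = p_target,
         n_proposed = 0L, n_accepted = 0L,
         recent_outcomes = logical(0),
         burn_in = as.integer(burn_in),
         local_window = as.integer(local_window),
         max_step = max_step),
    class = "adaptation_state"
  )
}

#' Record the outcome of a proposed exchange
#'
#' @param state An [adaptation_state()] object.
#' @param accepted Logical; was the proposed exchange accepted?
#' @return The updated state: `n_proposed` incremented, `n_accepted`
#'   incremented iff accepted, and the oldest entry of the local window
#'   evicted once it is at capacity.
#' @export
record_outcome <- function(state, accepted) {
  stopifnot(inherits(state, "adaptation_state"), is.logical(accepted),
            length(accepted) == 1L, !is.na(accepted))
  state$n_proposed <- state$n_proposed + 1L
  if (accepted) state$n_accepted <- state$n_accepted + 1L
  ro <- c(state$recent_outcomes, accepted)
  if (length(ro) > state$local_window)
    ro <- ro[(length(ro) - state$local_window + 1L):length(ro)]
  state$recent_outcomes <- ro
  state
}

#' Global acceptance fraction since the start of the run
#'
#' Includes proposals made during burn-in ("from the start of a run").
#'
#' @param state An [adaptation_state()] object.
#' @return Accepted/proposed fraction, or `NA` before any proposal.
#' @export
p_global <- function(state) {
  if (state$n_proposed == 0L) return(NA_real_)
  state$n_accepted / state$n_proposed
}

#' Local acceptance fraction over the most recent proposals
#'
#' Computed over however many outcomes exist, up to `local_window`.
#'
#' @param state An [adaptation_state()] object.
#' @return Accepted fraction of the recent window, or `NA` if empty.
#' @export
p_local <- function(state) {
  if (length(state$recent_outcomes) == 0L) return(NA_real_)
  mean(state$recent_outcomes)
}

#' Locally aware adaptation gate
#'
#' The spacing is only updated when the global and the local acceptance sit
#' strictly on the same side of the target: both above or both below. This
#' prevents updates driven by a stale global average when recent behaviour
#' already disagrees with it. No update happens within the burn-in period or
#' on exact ties with the target.
#'
#' @param state An [adaptation_state()] object.
#' @return `TRUE` iff the spacing may be updated now. `FALSE` on empty
#'   history.
#' @export
adaptation_gate <- function(state) {
  stopifnot(inherits(state, "adaptation_state"))
  if (state$n_proposed <= state$burn_in) return(FALSE)
  pg <- p_global(state)
  pl <- p_local(state)
  if (is.na(pg) || is.na(pl)) return(FALSE)
  pt <- state$p_target
  (pl > pt && pg > pt) || (pl < pt && pg < pt)
}

#' @export
print.adaptation_state <- function(x, ...) {
  cat(sprintf(
    "Adaptation state: target %.3f, %d/%d accepted (p_global = %s, p_local = %s)\n",
    x$p_target, x$n_accepted, x$n_proposed,
    format(p_global(x), digits = 3), format(p_local(x), digits = 3)))
  invisible(x)
}
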
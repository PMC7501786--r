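#' Run configuration for the coupled sampler
#'
#' Collects every knob of a Metropolis-coupled run. Defaults follow common
#' practice for adaptive tempering: swaps proposed every 100 iterations, a
#' target swap-acceptance probability of 0.234, spacing updates clamped to
#' 0.001 per proposed exchange after a burn-in of 100 proposed exchanges,
#' with the local acceptance window also covering the last 100 exchanges.
#'
#' @param n_chains Number of coupled chains (>= 1).
#' @param chain_length Number of iterations per chain; must be a multiple of
#'   `swap_interval`.
#' @param swap_interval Iterations between successive swap proposals
#'   (default 100).
#' @param target_acceptance Target swap-acceptance probability (default
#'   0.234).
#' @param ladder_scheme `"incremental"` or `"beta_quantile"` heating.
#' @param initial_spacing Initial ladder spacing (\eqn{\Delta t} or `b`).
#' @param swap_mode `"random"` (uniform over all chain pairs) or
#'   `"neighbour"` (uniform over adjacent temperature ranks).
#' @param log_every Trace-log thinning in iterations (default: the swap
#'   interval).
#' @param adapt Logical; tune the spacing during the run (default `TRUE`).
#' @param burn_in Proposed exchanges before any spacing update (default 100).
#' @param local_window Window of the local acceptance fraction (default 100).
#' @param max_step Clamp on a single spacing update (default 0.001).
#' @param heated_logging Also keep/write traces of the heated temperature
#'   ranks (default `FALSE`; the cold rank is always logged).
#' @param random_offset Draw the first swap iteration uniformly from
#'   `1..swap_interval` instead of proposing the first swap exactly at
#'   `swap_interval` (default `FALSE`). Subsequent swaps keep the same
#'   cadence either way.
#' @param optimise_operators Auto-tune tunable proposal scales toward a
#'   0.234 within-chain acceptance rate (default `FALSE`). Tuning state
#'   travels with the temperature rank across swaps.
#' @param output_dir Optional directory; when set, trace logs, the
#'   adaptation trace and a run manifest are written there.
#' @param run_label File-name stem for outputs (default `"mc3"`).
#' @param checkpoint Optional path; when set, a JSON checkpoint is written
#'   there at the end of the run.
#' @return An object of class `mc3_config`.
#' @export
mc3_config <- function(n_chains = 4L, chain_length = 100000L,
                       swap_interval = 100L, target_acceptance = 0.234,
                       ladder_scheme = c("incremental", "beta_quantile"),
                       initial_spacing = 0.01,
                       swap_mode = c("random", "neighbour"),
                       log_every = swap_interval, adapt = TRUE,
                       burn_in = 100L, local_window = 100L, max_step = 0.001,
                       heated_logging = FALSE, random_offset = FALSE,
                       optimise_operators = FALSE,
                       output_dir = NULL, run_label = "mc3",
                       checkpoint = NULL) {
  ladder_scheme <- match.arg(ladder_scheme)
  swap_mode <- match.arg(swap_mode)
  check_count(n_chains, "n_chains")
  check_count(chain_length, "chain_length")
  check_count(swap_interval, "swap_interval")
  check_count(log_every, "log_every")
  check_nonneg(initial_spacing, "initial_spacing")
  stopifnot(target_acceptance > 0, target_acceptance < 1)
  if (chain_length %% swap_interval != 0)
    stop("`chain_length` must be a multiple of `swap_interval`",
         call. = FALSE)
  structure(
    list(n_chains = as.integer(n_chains),
         chain_length = as.integer(chain_length),
         swap_interval = as.integer(swap_interval),
         target_acceptance = target_acceptance,
         ladder_scheme = ladder_scheme,
         initial_spacing = initial_spacing,
         swap_mode = swap_mode,
         log_every = as.integer(log_every),
         adapt = isTRUE(adapt),
         burn_in = as.integer(burn_in),
         local_window = as.integer(local_window),
         max_step = max_step,
         heated_logging = isTRUE(heated_logging),
         random_offset = isTRUE(random_offset),
         optimise_operators = isTRUE(optimise_operators),
         output_dir = output_dir, run_label = run_label,
         checkpoint = checkpoint),
    class = "mc3_config"
  )
}

# -- per-chain RNG streams ---------------------------------------------------
# One master seed spawns n chain streams plus a scheduler stream (swap-pair
# choice, random offset) and a swap-decision stream (the accept uniform).
# Chains therefore consume randomness independently of each other and of the
# swap machinery: between scheduled swaps their execution order is
# irrelevant, and a single-chain run is bit-identical to plain MCMC.

make_streams <- function(seed, k) {
  old <- get0(".Random.seed", envir = .GlobalEnv)
  old_kind <- RNGkind()
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
      do.call(RNGkind, as.list(old_kind))
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = .GlobalEnv)
  streams <- vector("list", k)
  for (i in seq_len(k)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- s
  }
  streams
}

with_stream <- function(e, i, expr) {
  assign(".Random.seed", e$streams[[i]], envir = .GlobalEnv)
  on.exit(e$streams[[i]] <- get(".Random.seed", envir = .GlobalEnv))
  expr
}

# -- swap mechanics ----------------------------------------------------------

#' Choose the pair of temperature ranks for a swap proposal
#'
#' In `"random"` mode the pair is uniform over all `choose(n, 2)` unordered
#' pairs; in `"neighbour"` mode it is uniform over the `n - 1` adjacent
#' temperature-rank pairs.
#'
#' @param n_chains Number of chains (>= 2).
#' @param mode `"random"` or `"neighbour"`.
#' @return Sorted integer pair of temperature ranks.
#' @export
propose_swap_pair <- function(n_chains, mode = c("random", "neighbour")) {
  mode <- match.arg(mode)
  check_count(n_chains, "n_chains")
  if (n_chains < 2L)
    stop("need at least 2 chains to propose a swap", call. = FALSE)
  if (mode == "neighbour") {
    r <- sample.int(n_chains - 1L, 1L)
    c(r, r + 1L)
  } else {
    sort(sample.int(n_chains, 2L))
  }
}

#' Exchange temperatures between two chains
#'
#' Applies an accepted swap: the two chains exchange their temperature rank,
#' their operator tuning (so operators stay optimised for the temperature
#' they serve) and their logger binding (so each log file keeps receiving
#' samples of one temperature, not of one chain). The model states and
#' cached evaluations are deliberately untouched — exchanging labels is
#' equivalent to exchanging states, and far cheaper for large states.
#'
#' @param chain_a,chain_b Two distinct chain-state lists as maintained by the
#'   engine (fields `chain_id`, `state`, `ev`, `rank`, `proposals`,
#'   `logger_binding`, tuning counters).
#' @return List of the two updated chains, in the order given.
#' @export
perform_swap <- function(chain_a, chain_b) {
  if (identical(chain_a$chain_id, chain_b$chain_id))
    stop("cannot swap a chain with itself", call. = FALSE)
  swap_fields <- c("rank", "proposals", "logger_binding",
                   "tune_accept", "tune_steps")
  for (f in swap_fields) {
    tmp <- chain_a[[f]]
    chain_a[[f]] <- chain_b[[f]]
    chain_b[[f]] <- tmp
  }
  list(chain_a, chain_b)
}

# -- engine ------------------------------------------------------------------

new_chain <- function(chain_id, state, ev, rank, proposals) {
  list(chain_id = chain_id, state = state, ev = ev, rank = rank,
       proposals = proposals, logger_binding = rank,
       tune_accept = 0L, tune_steps = 0L)
}

make_engine <- function(target, proposals, config, seed, init_state = NULL) {
  stopifnot(inherits(target, "mc3_target"), inherits(config, "mc3_config"))
  if (is.null(proposals)) proposals <- target$default_proposals
  if (is.null(proposals))
    stop("no proposals given and the target has no defaults", call. = FALSE)
  if (inherits(proposals, "mc3_proposal")) proposals <- list(proposals)
  n <- config$n_chains
  e <- new.env(parent = emptyenv())
  e$target <- target
  e$config <- config
  e$seed <- as.integer(seed)
  e$streams <- make_streams(seed, n + 2L)
  e$ladder <- temperature_ladder(n, config$ladder_scheme,
                                 config$initial_spacing)
  e$adapt <- adaptation_state(config$target_acceptance, config$burn_in,
                              config$local_window, config$max_step)
  e$iter <- 0L
  e$swap_offset <- if (config$random_offset && n >= 2L) {
    with_stream(e, n + 1L, sample.int(config$swap_interval, 1L))
  } else config$swap_interval
  e$chains <- vector("list", n)
  for (i in seq_len(n)) {
    st <- if (is.null(init_state)) with_stream(e, i, target$init())
          else init_state
    ev <- log_posterior_of(target, st)
    if (!is.finite(ev$log_posterior))
      stop("initial state of chain ", i, " has non-finite log posterior",
           call. = FALSE)
    e$chains[[i]] <- new_chain(i, st, ev[c("log_likelihood", "log_prior")],
                               i, proposals)
  }
  e$param_names <- names(target$params(e$chains[[1L]]$state))
  e
}

# Advance the engine by `n_iterations`, collecting logged rows, swap events
# and the adaptation trace for this segment only (resume-friendly).
run_segment <- function(e, n_iterations, log_initial = FALSE) {
  cfg <- e$config
  n <- cfg$n_chains
  si <- cfg$swap_interval
  end_iter <- e$iter + n_iterations
  n_rows <- (n_iterations %/% cfg$log_every) + as.integer(log_initial)
  n_swaps_max <- (n_iterations %/% si) + 1L
  ncol_tr <- 4L + length(e$param_names)
  trace_ranks <- if (cfg$heated_logging) seq_len(n) else 1L
  traces <- lapply(seq_len(n), function(r)
    if (r %in% trace_ranks) matrix(NA_real_, n_rows, ncol_tr) else NULL)
  trees <- if (!is.null(e$target$get_tree)) vector("list", n_rows) else NULL
  rank_hist <- matrix(NA_integer_, n_rows, n + 1L,
                      dimnames = list(NULL, c("iteration",
                                              paste0("chain_", seq_len(n)))))
  swap_ev <- matrix(NA_real_, n_swaps_max, 7L)
  adapt_tr <- matrix(NA_real_, n_swaps_max, 5L)
  row_i <- 0L
  swap_i <- 0L

  log_state <- function() {
    row_i <<- row_i + 1L
    for (ch in e$chains) {
      r <- ch$rank
      if (!is.null(traces[[r]])) {
        post <- ch$ev$log_likelihood + ch$ev$log_prior
        traces[[r]][row_i, ] <<- c(e$iter, post, ch$ev$log_likelihood,
                                   ch$ev$log_prior,
                                   e$target$params(ch$state))
      }
      if (r == 1L && !is.null(trees))
        trees[[row_i]] <<- e$target$get_tree(ch$state)
    }
    rank_hist[row_i, ] <<- c(e$iter,
                             vapply(e$chains, `[[`, integer(1), "rank"))
  }

  if (log_initial) log_state()

  next_multiple <- function(x, step, anchor = 0L) {
    # smallest anchor + k*step strictly greater than x
    anchor + step * ((x - anchor) %/% step + 1L)
  }

  while (e$iter < end_iter) {
    nxt_log <- next_multiple(e$iter, cfg$log_every)
    nxt_swap <- if (n >= 2L) {
      if (e$iter < e$swap_offset) e$swap_offset
      else next_multiple(e$iter, si, e$swap_offset)
    } else Inf
    upto <- min(nxt_log, nxt_swap, end_iter)
    steps <- as.integer(upto - e$iter)
    for (i in seq_len(n)) {
      ch <- e$chains[[i]]
      beta <- e$ladder$betas[ch$rank]
      res <- with_stream(e, i,
        advance_chain(e$target, ch$proposals, ch$state, ch$ev, beta, steps))
      ch$state <- res$state
      ch$ev <- res$ev
      if (cfg$optimise_operators) {
        ch$tune_accept <- ch$tune_accept + res$n_accept
        ch$tune_steps <- ch$tune_steps + steps
        if (ch$tune_steps >= 200L) {
          ch <- tune_operators(ch)
        }
      }
      e$chains[[i]] <- ch
    }
    e$iter <- e$iter + steps

    if (n >= 2L && e$iter == nxt_swap) {
      pr <- with_stream(e, n + 1L, propose_swap_pair(n, cfg$swap_mode))
      ranks <- vapply(e$chains, `[[`, integer(1), "rank")
      ia <- which(ranks == pr[1L])
      ib <- which(ranks == pr[2L])
      post_a <- e$chains[[ia]]$ev$log_likelihood + e$chains[[ia]]$ev$log_prior
      post_b <- e$chains[[ib]]$ev$log_likelihood + e$chains[[ib]]$ev$log_prior
      la <- swap_log_accept(post_a, post_b,
                            e$ladder$betas[pr[1L]], e$ladder$betas[pr[2L]])
      u <- with_stream(e, n + 2L, runif(1))
      acc <- log(u) < la
      if (acc) {
        sw <- perform_swap(e$chains[[ia]], e$chains[[ib]])
        e$chains[[ia]] <- sw[[1L]]
        e$chains[[ib]] <- sw[[2L]]
      }
      e$adapt <- record_outcome(e$adapt, acc)
      gate <- adaptation_gate(e$adapt)
      if (cfg$adapt && gate) {
        e$ladder <- set_spacing(
          e$ladder,
          update_spacing(e$ladder$spacing, p_global(e$adapt),
                         e$adapt$p_target, e$adapt$n_proposed,
                         e$adapt$max_step))
      }
      swap_i <- swap_i + 1L
      swap_ev[swap_i, ] <- c(e$iter, pr[1L], pr[2L], ia, ib, la, acc)
      adapt_tr[swap_i, ] <- c(e$adapt$n_proposed, e$ladder$spacing,
                              p_global(e$adapt), p_local(e$adapt), gate)
      # paranoia: temperature ranks must always be a permutation of 1..n
      stopifnot(identical(sort(vapply(e$chains, `[[`, integer(1), "rank")),
                          seq_len(n)))
    }

    if (e$iter == nxt_log) log_state()
  }

  list(traces = lapply(traces, function(m) if (is.null(m)) NULL
                       else m[seq_len(row_i), , drop = FALSE]),
       trees = if (is.null(trees)) NULL else trees[seq_len(row_i)],
       rank_history = rank_hist[seq_len(row_i), , drop = FALSE],
       swap_events = swap_ev[seq_len(swap_i), , drop = FALSE],
       adaptation = adapt_tr[seq_len(swap_i), , drop = FALSE])
}

tune_operators <- function(ch) {
  rate <- ch$tune_accept / ch$tune_steps
  ch$proposals <- lapply(ch$proposals, function(p) {
    if (is.null(p$with_scale)) return(p)
    p$with_scale(p$scale * exp(0.5 * (rate - 0.234)))
  })
  ch$tune_accept <- 0L
  ch$tune_steps <- 0L
  ch
}

segment_result <- function(e, seg, files = NULL) {
  cn <- c("Sample", "posterior", "likelihood", "prior", e$param_names)
  traces <- lapply(seg$traces, function(m) {
    if (is.null(m)) return(NULL)
    colnames(m) <- cn
    m
  })
  se <- seg$swap_events
  colnames(se) <- c("iteration", "rank_a", "rank_b", "chain_a", "chain_b",
                    "log_accept", "accepted")
  ad <- seg$adaptation
  colnames(ad) <- c("exchange_index", "spacing", "p_global", "p_local",
                    "gate_open")
  rh <- seg$rank_history
  npro <- e$adapt$n_proposed
  structure(
    list(traces = traces, trees = seg$trees,
         swap_events = as.data.frame(se),
         adaptation = as.data.frame(ad),
         rank_history = rh,
         ladder = e$ladder,
         acceptance = list(
           n_proposed = npro, n_accepted = e$adapt$n_accepted,
           global = if (npro > 0L) e$adapt$n_accepted / npro else NA_real_),
         config = e$config, seed = e$seed, files = files),
    class = "mc3_result")
}

#' Run the adaptive Metropolis-coupled sampler
#'
#' Runs `config$n_chains` coupled chains for `config$chain_length` iterations
#' each. Every chain performs within-chain Metropolis-Hastings steps at its
#' current temperature; at the scheduled swap iterations a pair of
#' temperature ranks is proposed for exchange and, on acceptance, the two
#' chains trade temperatures (together with operator tuning and logger
#' binding) rather than states. After every proposed exchange the ladder
#' spacing is (optionally) tuned toward `config$target_acceptance` and the
#' new spacing is applied to all chains simultaneously. The temperature-rank-1
#' trace is the posterior sample; heated traces are retained only with
#' `heated_logging = TRUE`.
#'
#' All randomness flows from `seed` through dedicated per-chain streams plus
#' one scheduler and one swap-decision stream, so runs are reproducible and
#' chains are independent between swap points.
#'
#' @param target An [mc3_target()].
#' @param proposals List of [mc3_proposal()] objects (default: the target's).
#' @param config An [mc3_config()].
#' @param seed Integer master seed.
#' @param init_state Optional explicit initial state used for every chain
#'   (default: each chain draws its own via `target$init()`).
#' @return An object of class `mc3_result` with elements `traces` (one
#'   matrix per temperature rank; columns `Sample`, `posterior`,
#'   `likelihood`, `prior`, then model parameters), `swap_events`,
#'   `adaptation` (the spacing/acceptance trace), `rank_history`, `ladder`,
#'   `acceptance` (global swap-acceptance summary), `trees` (cold-chain
#'   genealogies, for tree targets), `config`, `seed` and `files`.
#' @seealso [run_mcmc()], [resume_mc3()], [mc3_config()]
#' @examples
#' res <- run_mc3(target_normal(dim = 2), config = mc3_config(
#'   n_chains = 2, chain_length = 2000), seed = 1)
#' res$acceptance$global
#' @export
run_mc3 <- function(target, proposals = NULL, config = mc3_config(),
                    seed = 1L, init_state = NULL) {
  e <- make_engine(target, proposals, config, seed, init_state)
  e$segment_start <- 0L
  seg <- run_segment(e, config$chain_length, log_initial = TRUE)
  files <- write_run_outputs(e, seg, first_segment = TRUE)
  if (!is.null(config$checkpoint)) write_checkpoint(e, config$checkpoint)
  segment_result(e, seg, files)
}

#' Run a plain (single-chain, unheated) MCMC
#'
#' The degenerate case of the coupled sampler: one cold chain, no swaps, no
#' adaptation. Uses the same proposal machinery, RNG-stream layout, and
#' logging cadence as [run_mc3()], so a coupled run with `n_chains = 1` and
#' the same seed reproduces this sampler's trace exactly.
#'
#' @inheritParams run_mc3
#' @param config An [mc3_config()]; `n_chains` is forced to 1.
#' @return An `mc3_result` (swap/adaptation tables empty).
#' @export
run_mcmc <- function(target, proposals = NULL, config = mc3_config(),
                     seed = 1L, init_state = NULL) {
  config$n_chains <- 1L
  if (is.null(proposals)) proposals <- target$default_proposals
  if (inherits(proposals, "mc3_proposal")) proposals <- list(proposals)
  e <- new.env(parent = emptyenv())
  e$target <- target
  e$config <- config
  e$seed <- as.integer(seed)
  e$streams <- make_streams(seed, 3L)
  e$ladder <- temperature_ladder(1L, config$ladder_scheme, 0)
  e$adapt <- adaptation_state(config$target_acceptance, config$burn_in,
                              config$local_window, config$max_step)
  e$iter <- 0L
  e$swap_offset <- config$swap_interval
  st <- if (is.null(init_state)) with_stream(e, 1L, target$init())
        else init_state
  ev <- log_posterior_of(target, st)
  if (!is.finite(ev$log_posterior))
    stop("initial state has non-finite log posterior", call. = FALSE)
  e$chains <- list(new_chain(1L, st, ev[c("log_likelihood", "log_prior")],
                             1L, proposals))
  e$param_names <- names(target$params(st))
  e$segment_start <- 0L
  seg <- run_segment(e, config$chain_length, log_initial = TRUE)
  files <- write_run_outputs(e, seg, first_segment = TRUE)
  segment_result(e, seg, files)
}

#' @export
print.mc3_result <- function(x, ...) {
  cat(sprintf("Coupled MCMC run: %d chain(s), %d iterations, seed %d\n",
              x$config$n_chains, x$config$chain_length, x$seed))
  cat(sprintf("  ladder: %s, final spacing %.6g\n",
              x$ladder$scheme, x$ladder$spacing))
  if (x$acceptance$n_proposed > 0)
    cat(sprintf("  swap acceptance: %d/%d = %.4f (target %.3f)\n",
                x$acceptance$n_accepted, x$acceptance$n_proposed,
                x$acceptance$global, x$config$target_acceptance))
  cat(sprintf("  cold trace: %d samples of %d columns\n",
              nrow(x$traces[[1L]]), ncol(x$traces[[1L]])))
  invisible(x)
}

#' Extract a cold-chain trace column
#'
#' @param result An `mc3_result`.
#' @param column Column name (default `"posterior"`).
#' @param burn_in_frac Fraction of initial samples to discard (default 0).
#' @return Numeric vector.
#' @export
cold_trace <- function(result, column = "posterior", burn_in_frac = 0) {
  m <- result$traces[[1L]]
  v <- m[, column]
  if (burn_in_frac > 0) v <- v[-seq_len(floor(length(v) * burn_in_frac))]
  v
}
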
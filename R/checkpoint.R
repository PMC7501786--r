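# Versioned JSON checkpoints. Every floating-point quantity is stored as a
# "%.17g" string so states, cached evaluations, the ladder spacing and the
# logged traces continue bit-for-bit after a resume; RNG stream states are
# stored as the underlying integer vectors.

CHECKPOINT_VERSION <- 1L

#' Write an engine checkpoint
#'
#' Serializes the complete sampler state — chain states and cached
#' evaluations, temperature ranks, operator scales, ladder, adaptation
#' bookkeeping, all RNG streams and the iteration counter — to a versioned
#' JSON document. A run of length L stopped at L/2 and resumed produces the
#' same logged samples as an unbroken run with the same seed.
#'
#' `run_mc3()` calls this automatically at the end of a run when
#' `config$checkpoint` is set; it is exported for engine-level tooling.
#'
#' @param e Engine environment (internal; as created by `run_mc3()`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [resume_mc3()], [read_checkpoint()]
#' @export
write_checkpoint <- function(e, path) {
  cfg <- e$config
  chains <- lapply(e$chains, function(ch) {
    list(chain_id = ch$chain_id,
         rank = ch$rank,
         logger_binding = ch$logger_binding,
         state = e$target$serialize(ch$state),
         log_likelihood = fmt17(ch$ev$log_likelihood),
         log_prior = fmt17(ch$ev$log_prior),
         scales = lapply(ch$proposals, function(p)
           if (is.null(p$scale)) NULL else fmt17(p$scale)),
         tune_accept = ch$tune_accept,
         tune_steps = ch$tune_steps)
  })
  doc <- list(
    format = "adaptMC3-checkpoint",
    version = CHECKPOINT_VERSION,
    package_version = as.character(utils::packageVersion("adaptMC3")),
    seed = e$seed,
    iteration = e$iter,
    swap_offset = e$swap_offset,
    config = config_as_list(cfg),
    target = list(label = e$target$label,
                  kernel_id = if (is.null(e$target$kernel)) NULL
                              else e$target$kernel$id,
                  kernel_pars = if (is.null(e$target$kernel)) NULL
                                else fmt17(e$target$kernel$pars)),
    ladder = list(n_chains = e$ladder$n_chains, scheme = e$ladder$scheme,
                  spacing = fmt17(e$ladder$spacing)),
    adaptation = list(p_target = e$adapt$p_target,
                      n_proposed = e$adapt$n_proposed,
                      n_accepted = e$adapt$n_accepted,
                      recent_outcomes = as.integer(e$adapt$recent_outcomes),
                      burn_in = e$adapt$burn_in,
                      local_window = e$adapt$local_window,
                      max_step = e$adapt$max_step),
    chains = chains,
    streams = lapply(e$streams, as.integer))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read and validate a checkpoint file
#'
#' @param path Checkpoint path.
#' @return The parsed checkpoint document (a list).
#' @export
read_checkpoint <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(cond)
                    stop("cannot parse checkpoint '", path, "': ",
                         conditionMessage(cond), call. = FALSE))
  if (!identical(doc$format, "adaptMC3-checkpoint"))
    stop("'", path, "' is not an adaptMC3 checkpoint", call. = FALSE)
  if (is.null(doc$version) || doc$version > CHECKPOINT_VERSION)
    stop("checkpoint version ", doc$version,
         " is newer than this package supports (", CHECKPOINT_VERSION, ")",
         call. = FALSE)
  doc
}

rebuild_builtin_target <- function(doc) {
  id <- doc$target$kernel_id
  if (is.null(id)) return(NULL)
  pars <- as.numeric(unlist(doc$target$kernel_pars))
  if (id == 1L) target_normal(dim = pars[1L], sd = pars[2L])
  else if (id == 2L) make_island_target(n_islands = pars[1L], sd = pars[2L],
                                        barrier_depth = pars[3L])
  else NULL
}

#' Resume a checkpointed run
#'
#' Restores the full engine state from a checkpoint and continues for
#' `additional_iterations` more iterations per chain. With the same target,
#' this extends the original run exactly: the logged samples equal those an
#' unbroken longer run would have produced. New trace rows are appended to
#' the run's log files when the configuration has an `output_dir`.
#'
#' Built-in toy targets are reconstructed automatically from the checkpoint;
#' any other target (e.g. the phylogenetic testbed, whose likelihood depends
#' on the alignment) must be passed again via `target`.
#'
#' @param path Checkpoint path.
#' @param additional_iterations Iterations per chain to append; must be a
#'   multiple of the configured swap interval. Zero is allowed and produces
#'   no new rows.
#' @param target Optional [mc3_target()]; required for non-built-in targets.
#' @param proposals Optional proposal list (default: target defaults);
#'   checkpointed operator scales are re-applied to tunable proposals.
#' @return An `mc3_result` covering only the appended segment.
#' @export
resume_mc3 <- function(path, additional_iterations, target = NULL,
                       proposals = NULL) {
  doc <- read_checkpoint(path)
  if (additional_iterations < 0)
    stop("`additional_iterations` must be >= 0", call. = FALSE)
  cfg_l <- doc$config
  cfg <- mc3_config(
    n_chains = cfg_l$n_chains, chain_length = cfg_l$chain_length,
    swap_interval = cfg_l$swap_interval,
    target_acceptance = cfg_l$target_acceptance,
    ladder_scheme = cfg_l$ladder_scheme,
    initial_spacing = cfg_l$initial_spacing, swap_mode = cfg_l$swap_mode,
    log_every = cfg_l$log_every, adapt = cfg_l$adapt,
    burn_in = cfg_l$burn_in, local_window = cfg_l$local_window,
    max_step = cfg_l$max_step, heated_logging = cfg_l$heated_logging,
    random_offset = cfg_l$random_offset,
    optimise_operators = cfg_l$optimise_operators,
    output_dir = cfg_l$output_dir,
    run_label = if (is.null(cfg_l$run_label)) "mc3" else cfg_l$run_label,
    checkpoint = cfg_l$checkpoint)
  if (additional_iterations %% cfg$swap_interval != 0)
    stop("`additional_iterations` must be a multiple of the swap interval",
         call. = FALSE)
  if (is.null(target)) target <- rebuild_builtin_target(doc)
  if (is.null(target))
    stop("this checkpoint's target cannot be reconstructed automatically; ",
         "pass `target` explicitly", call. = FALSE)
  if (is.null(proposals)) proposals <- target$default_proposals
  if (inherits(proposals, "mc3_proposal")) proposals <- list(proposals)

  e <- new.env(parent = emptyenv())
  e$target <- target
  e$config <- cfg
  e$seed <- as.integer(doc$seed)
  e$iter <- as.integer(doc$iteration)
  e$swap_offset <- as.integer(doc$swap_offset)
  e$streams <- lapply(doc$streams, function(s) as.integer(unlist(s)))
  e$ladder <- temperature_ladder(cfg$n_chains, doc$ladder$scheme,
                                 as.numeric(doc$ladder$spacing))
  ad <- adaptation_state(doc$adaptation$p_target, doc$adaptation$burn_in,
                         doc$adaptation$local_window,
                         doc$adaptation$max_step)
  ad$n_proposed <- as.integer(doc$adaptation$n_proposed)
  ad$n_accepted <- as.integer(doc$adaptation$n_accepted)
  ad$recent_outcomes <-
    as.logical(as.integer(unlist(doc$adaptation$recent_outcomes)))
  if (length(ad$recent_outcomes) == 0L) ad$recent_outcomes <- logical(0)
  e$adapt <- ad
  e$chains <- lapply(doc$chains, function(cd) {
    props <- proposals
    for (k in seq_along(props)) {
      sc <- cd$scales[[k]]
      if (!is.null(sc) && !is.null(props[[k]]$with_scale))
        props[[k]] <- props[[k]]$with_scale(as.numeric(sc))
    }
    ch <- new_chain(as.integer(cd$chain_id),
                    target$deserialize(cd$state),
                    list(log_likelihood = as.numeric(cd$log_likelihood),
                         log_prior = as.numeric(cd$log_prior)),
                    as.integer(cd$rank), props)
    ch$logger_binding <- as.integer(cd$logger_binding)
    ch$tune_accept <- as.integer(cd$tune_accept)
    ch$tune_steps <- as.integer(cd$tune_steps)
    ch
  })
  e$param_names <- names(target$params(e$chains[[1L]]$state))
  e$segment_start <- e$iter
  seg <- run_segment(e, as.integer(additional_iterations),
                     log_initial = FALSE)
  files <- write_run_outputs(e, seg, first_segment = FALSE)
  if (!is.null(cfg$checkpoint)) write_checkpoint(e, cfg$checkpoint)
  segment_result(e, seg, files)
}
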
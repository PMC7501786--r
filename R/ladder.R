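#' Incremental temperature ladder
#'
#' Computes the chain temperatures \eqn{\beta_i = 1 / (1 + (i - 1)\Delta t)}
#' for chains \eqn{i = 1, \dots, n}. The first chain is always cold
#' (\eqn{\beta_1 = 1}); a single spacing parameter \eqn{\Delta t} controls how
#' quickly the remaining chains heat up, which is what makes the ladder
#' tunable by a single scalar during a run.
#'
#' @param n_chains Number of chains (integer, >= 1).
#' @param delta_t Temperature spacing \eqn{\Delta t} (>= 0). Zero collapses the
#'   ladder so that every chain is cold.
#' @return Numeric vector of length `n_chains`, non-increasing, in (0, 1],
#'   with first element exactly 1.
#' @seealso [beta_quantile_betas()], [temperature_ladder()]
#' @examples
#' incremental_betas(4, 0.1)
#' @export
incremental_betas <- function(n_chains, delta_t) {
  check_count(n_chains, "n_chains")
  check_nonneg(delta_t, "delta_t")
  1 / (1 + (seq_len(n_chains) - 1) * delta_t)
}

#' Beta-quantile temperature ladder
#'
#' Computes chain temperatures from the quantiles of a Beta(1, b)
#' distribution: \eqn{\beta_i = 1 - F((i-1)/n)} where \eqn{F} is the
#' Beta(1, b) cumulative distribution function. Since
#' \eqn{F(x) = 1 - (1 - x)^b} for \eqn{\alpha = 1}, this is evaluated in
#' closed form as \eqn{(1 - (i-1)/n)^b}; the closed form is exact, so no
#' special-function evaluation is needed. The division is by `n_chains`
#' (not `n_chains - 1`) so the hottest chain keeps \eqn{\beta > 0}.
#'
#' @param n_chains Number of chains (integer, >= 1).
#' @param b Tuning parameter of the Beta(1, b) distribution (>= 0). Zero
#'   collapses the ladder; larger values heat the hot end faster.
#' @return Numeric vector of length `n_chains`, non-increasing, in (0, 1],
#'   with first element exactly 1.
#' @seealso [incremental_betas()], [temperature_ladder()]
#' @examples
#' beta_quantile_betas(4, 1)   # linear ladder 1, .75, .5, .25
#' @export
beta_quantile_betas <- function(n_chains, b) {
  check_count(n_chains, "n_chains")
  check_nonneg(b, "b")
  (1 - (seq_len(n_chains) - 1) / n_chains)^b
}

#' Temperature ladder object
#'
#' Bundles the number of chains, the heating scheme and the single spacing
#' parameter, together with the resulting temperature vector. The spacing is
#' a single scalar under both schemes so the adaptive tuning machinery is
#' scheme-agnostic.
#'
#' @param n_chains Number of chains (integer, >= 1).
#' @param scheme `"incremental"` for \eqn{\beta_i = 1/(1 + (i-1)\Delta t)} or
#'   `"beta_quantile"` for Beta(1, b)-quantile spacing.
#' @param spacing The spacing parameter (\eqn{\Delta t} or `b`), >= 0.
#' @return An object of class `temperature_ladder` with fields `n_chains`,
#'   `scheme`, `spacing` and `betas`.
#' @examples
#' temperature_ladder(4, "incremental", 0.1)
#' @export
temperature_ladder <- function(n_chains,
                               scheme = c("incremental", "beta_quantile"),
                               spacing = 0.01) {
  scheme <- match.arg(scheme)
  betas <- ladder_betas(n_chains, scheme, spacing)
  structure(
    list(n_chains = as.integer(n_chains), scheme = scheme,
         spacing = spacing, betas = betas),
    class = "temperature_ladder"
  )
}

#' Recompute a ladder with a new spacing
#'
#' Used by the adaptation step: the new spacing is applied to all chains
#' simultaneously by regenerating the whole temperature vector.
#'
#' @param ladder A [temperature_ladder()] object.
#' @param spacing New spacing value (>= 0).
#' @return The updated `temperature_ladder`.
#' @export
set_spacing <- function(ladder, spacing) {
  stopifnot(inherits(ladder, "temperature_ladder"))
  ladder$spacing <- spacing
  ladder$betas <- ladder_betas(ladder$n_chains, ladder$scheme, spacing)
  ladder
}

ladder_betas <- function(n_chains, scheme, spacing) {
  switch(scheme,
    incremental = incremental_betas(n_chains, spacing),
    beta_quantile = beta_quantile_betas(n_chains, spacing),
    stop("unknown ladder scheme: ", scheme)
  )
}

#' @export
print.temperature_ladder <- function(x, ...) {
  cat(sprintf("Temperature ladder: %d chains, %s scheme, spacing = %g\n",
              x$n_chains, x$scheme, x$spacing))
  cat("betas:", paste(signif(x$betas, 6), collapse = " "), "\n")
  invisible(x)
}

# -- argument checks shared across modules -----------------------------------

check_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != as.integer(x))
    stop(sprintf("`%s` must be a single positive integer", name),
         call. = FALSE)
  invisible(TRUE)
}

check_nonneg <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("`%s` must be a single non-negative number", name),
         call. = FALSE)
  invisible(TRUE)
}
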
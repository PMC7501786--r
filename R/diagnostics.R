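#' Effective sample size of a trace
#'
#' Estimates the effective sample size `N / (1 + 2 * sum(rho_k))`, with the
#' autocorrelation sum truncated by Geyer's initial-positive-sequence rule:
#' autocorrelations are added in adjacent pairs `(rho_1 + rho_2)`,
#' `(rho_3 + rho_4)`, ... and summation stops before the first pair whose
#' sum is non-positive. The result is clipped to `(0, N]`. This truncation
#' differs in dialect from the fixed-maximum-lag estimators in some trace
#' analysers, so small numeric differences from those tools are expected.
#'
#' @param trace Numeric vector, length >= 10.
#' @param max_lag Largest lag considered (default `min(N - 1, 10000)`).
#' @return The ESS estimate; `NA` (the documented undefined-ESS sentinel)
#'   for a constant trace.
#' @examples
#' effective_sample_size(rnorm(1000))  # near 1000
#' @export
effective_sample_size <- function(trace, max_lag = min(length(trace) - 1L,
                                                       10000L)) {
  n <- length(trace)
  if (n < 10L) stop("trace too short for an ESS estimate", call. = FALSE)
  if (stats::var(trace) == 0) return(NA_real_)
  rho <- as.numeric(stats::acf(trace, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)[-1L]  # drop lag 0
  s <- 0
  t <- 1L
  while (t <= length(rho)) {
    g <- rho[t] + if (t + 1L <= length(rho)) rho[t + 1L] else 0
    if (g <= 0) break
    s <- s + g
    t <- t + 2L
  }
  ess <- n / (1 + 2 * s)
  min(max(ess, .Machine$double.eps), n)
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' The supremum over x of the absolute difference between the two empirical
#' cumulative distribution functions.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return The KS distance, in `[0, 1]`.
#' @examples
#' ks_distance(rnorm(100), rnorm(100))
#' @export
ks_distance <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("samples must be non-empty", call. = FALSE)
  x <- sort(unique(c(sample_a, sample_b)))
  fa <- stats::ecdf(sample_a)(x)
  fb <- stats::ecdf(sample_b)(x)
  max(abs(fa - fb))
}

#' Clade support frequencies of a tree sample
#'
#' For every clade (descendant taxon set of an internal node, root
#' included), the fraction of sampled trees that contain it.
#'
#' @param trees List of `mc3_tree` objects over the same taxa.
#' @return A named numeric vector of class `clade_table`: names are
#'   canonical comma-joined sorted taxon sets, values are frequencies in
#'   `[0, 1]`; the all-taxa clade has frequency 1.
#' @export
clade_frequencies <- function(trees) {
  stopifnot(length(trees) >= 1L)
  taxa <- sort(trees[[1L]]$taxa)
  counts <- new.env(parent = emptyenv())
  for (tr in trees) {
    if (!identical(sort(tr$taxa), taxa))
      stop("trees have mismatched taxa", call. = FALSE)
    keys <- unique(vapply(tree_clades(tr), paste, "", collapse = ","))
    for (k in keys)
      assign(k, (get0(k, counts, ifnotfound = 0)) + 1L, envir = counts)
  }
  keys <- ls(counts)
  freq <- vapply(keys, get, numeric(1), envir = counts) / length(trees)
  structure(freq, taxa = taxa, n_trees = length(trees),
            class = "clade_table")
}

#' Maximal clade-support difference between two runs
#'
#' The maximum over the union of observed clades of the absolute difference
#' in support; a clade absent from one table counts as frequency 0 there.
#' Used to compare replicate runs against a reference (typically the
#' concatenation of all runs).
#'
#' @param run,reference `clade_table` objects over the same taxa.
#' @return The maximal absolute support difference, in `[0, 1]`.
#' @export
max_clade_support_difference <- function(run, reference) {
  stopifnot(inherits(run, "clade_table"), inherits(reference, "clade_table"))
  if (!identical(attr(run, "taxa"), attr(reference, "taxa")))
    stop("clade tables are over different taxa", call. = FALSE)
  keys <- union(names(run), names(reference))
  a <- ifelse(keys %in% names(run), run[keys], 0)
  b <- ifelse(keys %in% names(reference), reference[keys], 0)
  max(abs(a - b))
}

#' Concatenate tree samples and tabulate clade support
#'
#' Builds the reference clade table from several runs by concatenating
#' their tree samples, with an optional leave-out of one run (so a run is
#' not compared against a reference that contains itself).
#'
#' @param tree_samples List of lists of `mc3_tree` objects.
#' @param leave_out Optional index of a run to exclude.
#' @return A `clade_table`.
#' @export
reference_clade_table <- function(tree_samples, leave_out = NULL) {
  if (!is.null(leave_out)) tree_samples <- tree_samples[-leave_out]
  clade_frequencies(do.call(c, tree_samples))
}

#' Diagnostic report over one or more runs
#'
#' Reads trace logs (and optionally NEXUS tree logs), discards an initial
#' burn-in fraction, and reports per-column ESS for each run, the pairwise
#' KS distance matrix of a chosen column, and — when tree logs are given —
#' each run's maximal clade-support difference from the concatenated
#' reference.
#'
#' @param trace_paths Character vector of trace-log paths.
#' @param tree_paths Optional character vector of NEXUS tree-log paths
#'   (parallel to `trace_paths`).
#' @param column Column for the KS comparison (default `"posterior"`).
#' @param burn_in_frac Fraction of each trace discarded as burn-in
#'   (default 0.1).
#' @param out Optional path; when given, the report is written there as a
#'   tab-separated file.
#' @return A list with elements `ess` (runs x columns matrix), `ks`
#'   (runs x runs matrix) and `clade_diff` (vector or `NULL`).
#' @export
diagnose_runs <- function(trace_paths, tree_paths = NULL,
                          column = "posterior", burn_in_frac = 0.1,
                          out = NULL) {
  stopifnot(length(trace_paths) >= 1L)
  traces <- lapply(trace_paths, read_trace_log)
  chop <- function(df) {
    keep <- seq_len(nrow(df)) > floor(nrow(df) * burn_in_frac)
    df[keep, , drop = FALSE]
  }
  traces <- lapply(traces, chop)
  cols <- setdiff(colnames(traces[[1L]]), "Sample")
  ess <- do.call(rbind, lapply(traces, function(df)
    vapply(cols, function(cn) {
      v <- df[[cn]]
      if (stats::var(v) == 0) NA_real_ else effective_sample_size(v)
    }, numeric(1))))
  rownames(ess) <- basename(trace_paths)
  nr <- length(traces)
  ks <- matrix(0, nr, nr,
               dimnames = list(basename(trace_paths),
                               basename(trace_paths)))
  for (i in seq_len(nr)) for (j in seq_len(nr)) if (i < j)
    ks[i, j] <- ks[j, i] <- ks_distance(traces[[i]][[column]],
                                        traces[[j]][[column]])
  clade_diff <- NULL
  if (!is.null(tree_paths)) {
    samples <- lapply(tree_paths, function(p) {
      trs <- read_tree_log(p)
      trs[seq_len(length(trs)) > floor(length(trs) * burn_in_frac)]
    })
    clade_diff <- vapply(seq_along(samples), function(i)
      max_clade_support_difference(
        clade_frequencies(samples[[i]]),
        reference_clade_table(samples, leave_out = if (length(samples) > 1L)
          i else NULL)),
      numeric(1))
    names(clade_diff) <- basename(tree_paths)
  }
  res <- list(ess = ess, ks = ks, clade_diff = clade_diff)
  if (!is.null(out)) write_diagnostics_report(res, out)
  res
}

write_diagnostics_report <- function(res, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("# adaptMC3 diagnostics report", con)
  writeLines("## ESS", con)
  writeLines(paste(c("run", colnames(res$ess)), collapse = "\t"), con)
  for (i in seq_len(nrow(res$ess)))
    writeLines(paste(c(rownames(res$ess)[i],
                       sprintf("%.6g", res$ess[i, ])), collapse = "\t"), con)
  writeLines("## KS", con)
  writeLines(paste(c("run", colnames(res$ks)), collapse = "\t"), con)
  for (i in seq_len(nrow(res$ks)))
    writeLines(paste(c(rownames(res$ks)[i],
                       sprintf("%.6g", res$ks[i, ])), collapse = "\t"), con)
  if (!is.null(res$clade_diff)) {
    writeLines("## max clade support difference vs reference", con)
    for (i in seq_along(res$clade_diff))
      writeLines(sprintf("%s\t%.6g", names(res$clade_diff)[i],
                         res$clade_diff[i]), con)
  }
  invisible(path)
}
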
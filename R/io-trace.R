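# Tab-separated trace logs in the dialect common to Bayesian phylogenetics
# tools (comment lines prefixed "#", a header row starting with "Sample",
# then one row per logged state). Values are written with 17 significant
# digits so that doubles round-trip exactly.

fmt17 <- function(x) sprintf("%.17g", x)

#' Initialize a trace log file
#'
#' Writes comment lines and the header row, overwriting any existing file.
#'
#' @param path File path.
#' @param columns Character vector of column names; the first must be
#'   `"Sample"`.
#' @param comments Character vector of comment lines (written prefixed
#'   with `"#"`).
#' @return `path`, invisibly.
#' @export
trace_log_init <- function(path, columns, comments = character()) {
  if (columns[1L] != "Sample")
    stop("first trace column must be 'Sample'", call. = FALSE)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("#", cm), con)
  writeLines(paste(columns, collapse = "\t"), con)
  invisible(path)
}

#' Append rows to a trace log
#'
#' @param path File path previously initialized by [trace_log_init()].
#' @param rows Numeric matrix whose columns match the file's header; the
#'   `Sample` column is written as an integer, the rest at 17 significant
#'   digits.
#' @return `path`, invisibly.
#' @export
trace_log_append <- function(path, rows) {
  if (nrow(rows) == 0L) return(invisible(path))
  con <- file(path, open = "at")
  on.exit(close(con))
  body <- apply(rows, 1L, function(r)
    paste(c(sprintf("%d", as.integer(r[1L])), fmt17(r[-1L])),
          collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Write a complete trace log
#'
#' Convenience wrapper around [trace_log_init()] + [trace_log_append()].
#'
#' @param path File path.
#' @param rows Numeric matrix with column names (first column `Sample`).
#' @param comments Comment lines.
#' @return `path`, invisibly.
#' @export
write_trace_log <- function(path, rows, comments = character()) {
  trace_log_init(path, colnames(rows), comments)
  trace_log_append(path, rows)
}

#' Read a trace log
#'
#' Parses a tab-separated trace log: lines starting with `#` are skipped,
#' the first remaining line must be a header whose first column is
#' `Sample`, and the `Sample` column must be non-decreasing. This reads both
#' this package's logs and the logs written by common Bayesian phylogenetics
#' engines.
#'
#' @param path File path.
#' @return A data frame, one column per logged quantity.
#' @export
read_trace_log <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines, "left"), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    stop("no header found in trace log '", path, "'", call. = FALSE)
  header <- strsplit(lines[idx[1L]], "\t", fixed = TRUE)[[1L]]
  if (header[1L] != "Sample")
    stop(sprintf("malformed trace header at line %d of '%s': %s",
                 idx[1L], path, "first column must be 'Sample'"),
         call. = FALSE)
  body_idx <- idx[-1L]
  vals <- lapply(body_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header))
      stop(sprintf("line %d of '%s' has %d fields, expected %d",
                   i, path, length(f), length(header)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v))
      stop(sprintf("non-numeric value at line %d of '%s'", i, path),
           call. = FALSE)
    v
  })
  m <- do.call(rbind, vals)
  if (is.null(m)) m <- matrix(numeric(0), 0L, length(header))
  colnames(m) <- header
  if (nrow(m) > 1L && any(diff(m[, "Sample"]) < 0)) {
    bad <- which(diff(m[, "Sample"]) < 0)[1L] + 1L
    stop(sprintf("non-monotone Sample column at line %d of '%s'",
                 body_idx[bad], path), call. = FALSE)
  }
  as.data.frame(m)
}

# -- run outputs -------------------------------------------------------------

trace_path <- function(dir, label, rank) {
  file.path(dir, sprintf("%s.rank%d.log", label, rank))
}

write_run_outputs <- function(e, seg, first_segment) {
  cfg <- e$config
  if (is.null(cfg$output_dir)) return(NULL)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  label <- cfg$run_label
  n <- cfg$n_chains
  ranks <- if (cfg$heated_logging) seq_len(n) else 1L
  cn <- c("Sample", "posterior", "likelihood", "prior", e$param_names)
  paths <- character(0)
  for (r in ranks) {
    p <- trace_path(cfg$output_dir, label, r)
    if (first_segment) {
      trace_log_init(p, cn, comments = c(
        sprintf(" adaptMC3 trace, temperature rank %d of %d", r, n),
        sprintf(" target=%s seed=%d", e$target$label, e$seed)))
    }
    trace_log_append(p, seg$traces[[r]])
    paths <- c(paths, p)
  }
  adapt_path <- file.path(cfg$output_dir, paste0(label, ".adaptation.tsv"))
  if (first_segment) {
    trace_log_init(adapt_path,
                   c("Sample", "spacing", "p_global", "p_local", "gate_open"))
  }
  if (nrow(seg$adaptation) > 0L) trace_log_append(adapt_path, seg$adaptation)
  tree_path <- NULL
  if (!is.null(seg$trees) && length(seg$trees) > 0L) {
    tree_path <- file.path(cfg$output_dir,
                           if (first_segment) paste0(label, ".trees.nexus")
                           else sprintf("%s.trees.from%d.nexus", label,
                                        e$segment_start))
    write_tree_log(seg$trees, tree_path,
                   iterations = seg$rank_history[, "iteration"])
  }
  manifest <- list(
    package = "adaptMC3",
    version = as.character(utils::packageVersion("adaptMC3")),
    seed = e$seed,
    config = config_as_list(cfg),
    target = e$target$label,
    trace_logs = as.list(paths),
    adaptation_log = adapt_path,
    tree_log = tree_path,
    checkpoint = cfg$checkpoint,
    start_iteration = e$segment_start,
    stop_iteration = e$iter)
  manifest_path <- file.path(cfg$output_dir, paste0(label, ".manifest.json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  list(trace_logs = paths, adaptation_log = adapt_path,
       tree_log = tree_path, manifest = manifest_path)
}

config_as_list <- function(cfg) {
  l <- unclass(cfg)
  l[!vapply(l, is.null, logical(1))]
}
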
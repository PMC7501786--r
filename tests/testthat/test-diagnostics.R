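test_that("ESS is near N for white noise and matches the AR(1) closed form", {
  set.seed(41)
  x <- rnorm(10000)
  expect_gt(effective_sample_size(x) / length(x), 0.8)
  expect_lte(effective_sample_size(x), length(x))
  # AR(1): integrated autocorrelation time (1+phi)/(1-phi)
  phi <- 0.9
  y <- ar1_series(100000, phi)
  ess <- effective_sample_size(y)
  expect_lt(abs(ess - length(y) * (1 - phi) / (1 + phi)) /
              (length(y) * (1 - phi) / (1 + phi)), 0.2)
  # monotone decreasing in phi
  set.seed(42)
  esss <- vapply(c(0.3, 0.6, 0.9), function(p)
    effective_sample_size(ar1_series(50000, p)), numeric(1))
  expect_true(all(diff(esss) < 0))
  # sentinels and preconditions
  expect_true(is.na(effective_sample_size(rep(1, 100))))
  expect_error(effective_sample_size(c(1, 2)), "too short")
})

test_that("KS distance equals the brute-force ECDF scan", {
  expect_identical(ks_distance(1:10, 1:10), 0)
  expect_identical(ks_distance(-(1:5), 1:7), 1)
  set.seed(43)
  for (i in 1:10) {
    a <- rnorm(50)
    b <- rnorm(80, mean = runif(1, -1, 1))
    expect_equal(ks_distance(a, b), brute_ks(a, b), tolerance = 1e-12)
    # metric properties
    expect_identical(ks_distance(a, b), ks_distance(b, a))
    cc <- rnorm(60)
    expect_lte(ks_distance(a, b),
               ks_distance(a, cc) + ks_distance(cc, b) + 1e-12)
  }
  expect_error(ks_distance(numeric(0), 1:3), "non-empty")
})

test_that("clade frequencies count descendant taxon sets", {
  t_ab <- read_newick("((A:1,B:1):1,(C:1,D:1):1);", text = TRUE)
  t_ac <- read_newick("((A:1,C:1):1,(B:1,D:1):1);", text = TRUE)
  tab <- clade_frequencies(list(t_ab, t_ab, t_ac))
  expect_equal(unname(tab["A,B"]), 2 / 3)
  expect_equal(unname(tab["A,B,C,D"]), 1)
  expect_equal(unname(tab["A,C"]), 1 / 3)
  # self-comparison is 0; disjoint topologies differ by 1
  expect_identical(max_clade_support_difference(tab, tab), 0)
  expect_identical(
    max_clade_support_difference(clade_frequencies(list(t_ab)),
                                 clade_frequencies(list(t_ac))), 1)
  # concatenation equals the sample-size weighted average
  s1 <- list(t_ab, t_ab, t_ac)
  s2 <- list(t_ac, t_ac)
  both <- clade_frequencies(c(s1, s2))
  f1 <- clade_frequencies(s1)
  f2 <- clade_frequencies(s2)
  keys <- names(both)
  g <- function(f, k) ifelse(k %in% names(f), f[k], 0)
  expect_equal(unname(both[keys]),
               unname((3 * g(f1, keys) + 2 * g(f2, keys)) / 5),
               tolerance = 1e-12)
  # leave-one-out reference
  ref <- reference_clade_table(list(s1, s2), leave_out = 2)
  expect_equal(unname(ref["A,B"]), 2 / 3)
})

test_that("diagnose_runs reports ESS, KS matrix and clade differences", {
  dir <- withr::local_tempdir()
  set.seed(44)
  paths <- character(2)
  tree_paths <- character(2)
  for (i in 1:2) {
    res <- run_mc3(target_phylo(n_taxa = 4),
                   config = mc3_config(n_chains = 1, chain_length = 5000,
                                       log_every = 50),
                   seed = i)
    paths[i] <- file.path(dir, sprintf("run%d.log", i))
    write_trace_log(paths[i], res$traces[[1]])
    tree_paths[i] <- file.path(dir, sprintf("run%d.trees", i))
    write_tree_log(res$trees, tree_paths[i])
  }
  out <- file.path(dir, "report.tsv")
  rep <- diagnose_runs(paths, tree_paths, out = out)
  expect_identical(dim(rep$ks), c(2L, 2L))
  expect_identical(rep$ks[1, 1], 0)
  expect_true(all(rep$ks >= 0 & rep$ks <= 1))
  expect_true(all(is.na(rep$ess) | rep$ess > 0))
  expect_length(rep$clade_diff, 2L)
  expect_true(file.exists(out))
  expect_match(readLines(out)[1], "diagnostics report")
})
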
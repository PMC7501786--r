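test_that("JC69 pruning matches closed forms and the enumeration oracle", {
  aln_same <- new_alignment(c("a", "b"), matrix(c("A", "A"), 2, 1))
  # zero path length: both tips forced to the root state
  tr0 <- two_taxon_tree(1e-300)
  expect_equal(jc69_log_likelihood(tr0, aln_same), log(0.25),
               tolerance = 1e-12)
  # two taxa, one site, same base, total path 0.3: reversibility closed form
  tr <- two_taxon_tree(0.15)
  expect_equal(jc69_log_likelihood(tr, aln_same),
               log(0.25 * (0.25 + 0.75 * exp(-0.4))), tolerance = 1e-12)
  aln_diff <- new_alignment(c("a", "b"), matrix(c("A", "G"), 2, 1))
  expect_equal(jc69_log_likelihood(tr, aln_diff),
               log(0.25 * (0.25 - 0.25 * exp(-0.4))), tolerance = 1e-12)
  # enumeration oracle on random 3- and 4-taxon trees, up to 3 sites
  set.seed(201)
  for (n in c(3, 4)) for (rep in 1:3) {
    tree <- simulate_coalescent_tree(n, 0.8)
    aln <- simulate_jc69_alignment(tree, 3)
    for (rate in c(0.5, 1)) {
      expect_equal(jc69_log_likelihood(tree, aln, rate),
                   enum_jc69_ll(tree, aln, rate), tolerance = 1e-10)
    }
  }
  expect_error(jc69_log_likelihood(tr, new_alignment("z",
    matrix("A", 1, 1))), "taxa")
})

test_that("coalescent density matches closed forms and integrates to one", {
  expect_equal(coalescent_log_density(two_taxon_tree(0.7), 1), -0.7)
  expect_equal(coalescent_log_density(two_taxon_tree(0.7), 2),
               -log(2) - 0.35)
  f <- Vectorize(function(t)
    exp(coalescent_log_density(two_taxon_tree(t), 1.7)))
  expect_equal(integrate(f, 0, Inf)$value, 1, tolerance = 1e-6)
  # scaling all heights and Ne by c shifts the log density by -(n-1) log c
  set.seed(7)
  tree <- simulate_coalescent_tree(6, 1)
  for (cc in c(0.5, 3)) {
    scaled <- tree
    scaled$heights <- scaled$heights * cc
    expect_equal(coalescent_log_density(scaled, cc),
                 coalescent_log_density(tree, 1) - 5 * log(cc),
                 tolerance = 1e-10)
  }
})

test_that("the coalescent simulator has the right TMRCA moments", {
  set.seed(31)
  t2 <- replicate(10000, tree_height(simulate_coalescent_tree(2, 1)))
  expect_lt(abs(mean(t2) - 1), 0.05)
  t10 <- replicate(10000, tree_height(simulate_coalescent_tree(10, 1)))
  expect_lt(abs(mean(t10) - 1.8), 0.1)
  for (i in 1:20) expect_silent(validate_tree(
    simulate_coalescent_tree(sample(2:9, 1), runif(1, 0.2, 3))))
})

test_that("the sequence simulator follows JC69 transition probabilities", {
  set.seed(32)
  tr <- two_taxon_tree(0.25)  # total path 0.5
  aln <- simulate_jc69_alignment(tr, 10000)
  p_exp <- 0.75 * (1 - exp(-4 * 0.5 / 3))
  expect_lt(abs(mean(aln$seqs[1, ] != aln$seqs[2, ]) - p_exp), 0.02)
  # zero rate: all sequences identical
  tr5 <- simulate_coalescent_tree(5, 1)
  a0 <- simulate_jc69_alignment(tr5, 50, rate = 0)
  expect_true(all(a0$seqs == rep(a0$seqs[1, ], each = 5)))
})

test_that("tree proposals preserve geometry, NNI is an involution", {
  set.seed(33)
  tree <- simulate_coalescent_tree(7, 1)
  for (i in 1:100) {
    mv <- propose_nni(tree)
    if (is.null(mv)) next
    expect_silent(validate_tree(mv$tree))
    expect_identical(mv$log_hastings, 0)
    expect_false(identical(adaptMC3:::topology_key(mv$tree),
                           adaptMC3:::topology_key(tree)))
    # applying the same exchange again restores the topology: find it by
    # scanning NNI moves of the new tree
    restored <- FALSE
    for (j in 1:200) {
      mv2 <- propose_nni(mv$tree)
      if (!is.null(mv2) &&
          identical(adaptMC3:::topology_key(mv2$tree),
                    adaptMC3:::topology_key(tree))) {
        restored <- TRUE
        break
      }
    }
    expect_true(restored)
    break
  }
  for (i in 1:50) {
    mv <- propose_uniform_node_height(tree)
    expect_silent(validate_tree(mv$tree))
    mv <- propose_height_scale(tree)
    expect_silent(validate_tree(mv$tree))
  }
  # scale move bookkeeping: k - 2 exponent, multiplier 1 is the identity
  n_int <- length(tree$taxa) - 1L
  set.seed(34)
  mv <- propose_height_scale(tree, sf = 0.75)
  m <- mv$tree$heights[length(tree$taxa) + 1L] /
    tree$heights[length(tree$taxa) + 1L]
  expect_equal(mv$log_hastings, (n_int - 2) * log(m), tolerance = 1e-12)
  pz <- propose_popsize_scale(2, sf = 0.75)
  expect_equal(pz$log_hastings, -log(pz$pop_size / 2), tolerance = 1e-12)
})

test_that("prior-only sampling recovers the coalescent topology law and the Ne prior", {
  # 4 taxa: the Kingman coalescent is uniform over ranked histories, so
  # each caterpillar topology has probability 1/18 and each balanced
  # topology 1/9. A prior-only run must reproduce this and the log-normal
  # Ne prior.
  tgt <- target_phylo(n_taxa = 4)
  res <- run_mcmc(tgt, config = mc3_config(chain_length = 150000,
                  log_every = 100), seed = 3)
  trees <- res$trees[-seq_len(150)]
  keys <- vapply(trees, adaptMC3:::topology_key, "")
  tab <- table(keys)
  expect_identical(length(tab), 15L)
  balanced <- vapply(names(tab), function(k) {
    sizes <- lengths(strsplit(strsplit(k, ";", fixed = TRUE)[[1]], ",",
                              fixed = TRUE))
    sum(sizes == 2) == 2
  }, logical(1))
  p_exp <- ifelse(balanced, 1 / 9, 1 / 18)
  pval <- chisq.test(as.numeric(tab), p = p_exp)$p.value
  expect_gt(pval, 0.01)
  # Ne marginal equals its log-normal(0, 1) prior
  ne <- cold_trace(res, "pop_size", burn_in_frac = 0.1)
  set.seed(91)
  ks <- suppressWarnings(ks.test(ne[seq(1, length(ne), by = 5)],
                                 rlnorm(5000)))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulated data can be re-inferred: Ne recovery at desk scale", {
  set.seed(11)
  truth <- simulate_coalescent_tree(6, 1)
  aln <- simulate_jc69_alignment(truth, 1000)
  res <- run_mc3(target_phylo(aln),
                 config = mc3_config(n_chains = 2, chain_length = 20000,
                                     log_every = 20), seed = 12)
  ne <- cold_trace(res, "pop_size", burn_in_frac = 0.25)
  expect_gt(median(ne), 0.5)
  expect_lt(median(ne), 2.0)
  th <- cold_trace(res, "tree_height", burn_in_frac = 0.25)
  expect_lt(abs(median(th) - tree_height(truth)) / tree_height(truth), 0.5)
})

test_that("island target has the advertised geometry", {
  tgt <- make_island_target(3, barrier_depth = 25, sd = 0.05)
  ld <- function(x) tgt$log_likelihood(x)
  peak <- ld(2)
  # valley floor sits barrier_depth below the peaks (flat plateau)
  expect_equal(ld(1.5) - peak, -25, tolerance = 0.01)
  expect_equal(ld(1.5), ld(2.5), tolerance = 1e-12)
  # single island: unimodal, no floor outside the mode range
  t1 <- make_island_target(1)
  expect_lt(t1$log_likelihood(1.5), t1$log_likelihood(1) - 25)
  # occupancy helper
  expect_equal(mode_occupancy(c(0.96, 2.1, 2.9, 3.2), 3),
               c(0.25, 0.25, 0.5))
})
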
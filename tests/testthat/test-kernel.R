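test_that("plain and heated acceptance follow the log-space rules", {
  expect_identical(mh_log_accept(-10, -10, 0), 0)
  expect_identical(mh_log_accept(-10, -12, 0), 0)
  expect_identical(mh_log_accept(-12, -10, 0), -2)
  expect_error(mh_log_accept(-1, -Inf, 0), "support")

  # beta = 1 recovers the unheated rule on a grid of inputs
  grid <- expand.grid(new = c(-20, -10.5, -3), old = c(-9, -4),
                      h = c(-0.7, 0, 1.2))
  for (i in seq_len(nrow(grid)))
    expect_identical(
      heated_log_accept(grid$new[i], grid$old[i], grid$h[i], 1),
      mh_log_accept(grid$new[i], grid$old[i], grid$h[i]))
  expect_identical(heated_log_accept(-12, -10, 0, 0.5), -1)
  # out-of-support proposals are rejected, not an error
  expect_identical(heated_log_accept(-Inf, -10, 0, 0.5), -Inf)
  # near-flat limit accepts symmetric proposals
  expect_gt(heated_log_accept(-1e6, -10, 0, 1e-12), -1e-3)
})

test_that("swap acceptance is symmetric in pair labelling", {
  expect_identical(swap_log_accept(-10, -50, 0.7, 0.7), 0)
  expect_identical(swap_log_accept(-10, -10, 1, 0.3), 0)
  expect_identical(swap_log_accept(-10, -8, 1.0, 0.8), 0)
  expect_equal(swap_log_accept(-8, -10, 1.0, 0.8), -0.4)
  set.seed(1)
  for (i in 1:25) {
    la <- runif(2, -50, 0)
    be <- runif(2, 0.05, 1)
    expect_equal(swap_log_accept(la[1], la[2], be[1], be[2]),
                 swap_log_accept(la[2], la[1], be[2], be[1]))
    expect_lte(swap_log_accept(la[1], la[2], be[1], be[2]), 0)
  }
  expect_identical(swap_log_accept(-Inf, -10, 1, 0.5), -Inf)
})

test_that("a heated chain targets the normalized beta-powered distribution", {
  # 3-state target, exact stationary distribution by eigen decomposition
  log_target <- log(c(0.6, 0.3, 0.1))
  for (beta in c(1, 0.55, 0.2)) {
    P <- heated_transition_matrix(log_target, beta)
    # the off-diagonal entries are exactly exp(heated_log_accept)/(k-1)
    for (i in 1:3) for (j in 1:3) if (i != j)
      expect_equal(P[i, j],
                   exp(heated_log_accept(log_target[j], log_target[i],
                                         0, beta)) / 2,
                   tolerance = 1e-14)
    pi_hat <- stationary_of(P)
    pi_beta <- exp(beta * log_target)
    pi_beta <- pi_beta / sum(pi_beta)
    expect_equal(pi_hat, pi_beta, tolerance = 1e-10)
  }
})

test_that("two coupled chains with swaps leave the cold marginal exactly on target", {
  # 2-state target, chains at beta 1 and 0.4; joint transition =
  # (within-chain sweep) then (swap proposal). Exact stationary cold
  # marginal must equal the target.
  log_target <- log(c(0.2, 0.8))
  betas <- c(1, 0.4)
  K <- lapply(betas, function(b) heated_transition_matrix(log_target, b))
  joint <- matrix(0, 4, 4)  # states (x1, x2) column-major: x1 fastest
  idx <- function(x1, x2) x1 + 2L * (x2 - 1L)
  for (x1 in 1:2) for (x2 in 1:2) for (y1 in 1:2) for (y2 in 1:2)
    joint[idx(x1, x2), idx(y1, y2)] <- K[[1]][x1, y1] * K[[2]][x2, y2]
  S <- matrix(0, 4, 4)
  for (x1 in 1:2) for (x2 in 1:2) {
    a <- exp(swap_log_accept(log_target[x1], log_target[x2],
                             betas[1], betas[2]))
    S[idx(x1, x2), idx(x2, x1)] <- S[idx(x1, x2), idx(x2, x1)] + a
    S[idx(x1, x2), idx(x1, x2)] <- S[idx(x1, x2), idx(x1, x2)] + (1 - a)
  }
  P <- joint %*% S
  pi_hat <- stationary_of(P)
  cold <- c(pi_hat[idx(1, 1)] + pi_hat[idx(1, 2)],
            pi_hat[idx(2, 1)] + pi_hat[idx(2, 2)])
  expect_equal(cold, exp(log_target), tolerance = 1e-10)
})
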
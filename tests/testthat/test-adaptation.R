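test_that("spacing update arithmetic matches the clamped, floored rule", {
  # zero discrepancy: no move
  expect_identical(update_spacing(0.1, 0.234, 0.234, 500), 0.1)
  # unclamped step: 0.266/1000
  expect_equal(update_spacing(0.1, 0.5, 0.234, 1000), 0.100266,
               tolerance = 1e-9)
  # clamped to +0.001
  expect_equal(update_spacing(0.1, 0.5, 0.234, 100), 0.101)
  # clamped to -0.001, then floored at zero
  expect_identical(update_spacing(0.0004, 0.0, 0.234, 150), 0)
  expect_error(update_spacing(0.1, 0.5, 0.234, 0), "positive integer")
})

test_that("spacing update is monotone in realized acceptance and bounded", {
  for (cur in c(0, 0.005, 0.3)) for (n in c(1, 10, 150, 10000)) {
    ps <- seq(0, 1, by = 0.05)
    out <- vapply(ps, function(p) update_spacing(cur, p, 0.234, n),
                  numeric(1))
    expect_true(all(diff(out) >= 0))            # monotone in p_global
    expect_true(all(abs(out - cur) <= 0.001 + 1e-15))
    expect_true(all(out >= 0))
    # self-correcting direction
    expect_true(all(out[ps > 0.234] >= cur))
    expect_true(all(out[ps < 0.234] <= cur))
  }
})

test_that("outcome recording tracks global and local acceptance", {
  st <- adaptation_state()
  st <- record_outcome(st, TRUE)
  expect_identical(st$n_proposed, 1L)
  expect_identical(st$n_accepted, 1L)
  expect_identical(p_global(st), 1)
  # 100 rejects then 1 accept with window 100
  st <- adaptation_state()
  for (i in 1:100) st <- record_outcome(st, FALSE)
  st <- record_outcome(st, TRUE)
  expect_equal(p_local(st), 0.01)
  expect_equal(p_global(st), 1 / 101)
  # capacity
  for (i in 1:49) st <- record_outcome(st, i %% 2 == 0)
  expect_length(st$recent_outcomes, 100L)
})

test_that("the gate requires burn-in passed and both fractions strictly on one side", {
  make <- function(pl, pg, n, window = 100L) {
    st <- adaptation_state(p_target = 0.234, local_window = window)
    # local window fully covered by the last `window` outcomes
    n_old <- n - window
    acc_local <- round(pl * window)
    acc_old <- round(pg * n) - acc_local
    stopifnot(n_old >= 0, acc_old >= 0, acc_old <= n_old)
    for (i in seq_len(n_old)) st <- record_outcome(st, i <= acc_old)
    for (i in seq_len(window)) st <- record_outcome(st, i <= acc_local)
    st
  }
  expect_true(adaptation_gate(make(0.30, 0.30, 150)))
  expect_false(adaptation_gate(make(0.20, 0.30, 150)))
  # within burn-in
  st <- adaptation_state()
  for (i in 1:50) st <- record_outcome(st, i <= 15)
  expect_false(adaptation_gate(st))
  # empty history
  expect_false(adaptation_gate(adaptation_state()))
  # both below
  expect_true(adaptation_gate(make(0.10, 0.12, 300)))
  # exact tie with the target is not an update
  st <- adaptation_state(p_target = 0.5, local_window = 10L)
  for (i in 1:200) st <- record_outcome(st, i %% 2 == 0)
  expect_identical(p_local(st), 0.5)
  expect_false(adaptation_gate(st))
})

test_that("late-run spacing updates vanish as O(1/exchanges)", {
  res <- run_mc3(target_normal(dim = 20),
                 config = mc3_config(n_chains = 4, chain_length = 3e5,
                                     initial_spacing = 0.01),
                 seed = 42)
  sp <- res$adaptation$spacing
  for (n0 in c(1200, 2000)) {
    win <- sp[n0:(n0 + 1000)]
    expect_lt(max(win) - min(win), 1000 * (1 / n0))
  }
})
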
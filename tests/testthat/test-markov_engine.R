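test_that("state space has the required structure", {
  states <- state_space()
  expect_length(states, 18)
  expect_length(attr(states, "tunnel"), 12)
  expect_equal(states[attr(states, "tunnel")], paste0("NMR", 1:12))
  expect_equal(states[length(states)], "Death")
})

test_that("transition matrices respect published rows and structural zeros", {
  M <- build_transition_matrix(k = 20, p_exit = 0.01, q_bg = 0,
                               shares = c(locoregional = 0.25,
                                          metastatic = 0.6, death = 0.15),
                               p_rem_1l = 0.0076, p_1l_2l = 0.0428,
                               p_2l_death = 0.0315)
  # remission row with no background death carries the published probability
  expect_equal(M["Remission", "FirstLineMet"], 0.0076)
  expect_equal(M["Remission", "Remission"], 1 - 0.0076)
  # death is absorbing
  expect_equal(unname(M["Death", ]), c(rep(0, 17), 1))
  # no edge from any recurrence tunnel compartment to first-line metastatic
  for (j in 1:12) expect_equal(M[paste0("NMR", j), "FirstLineMet"], 0)
  # tunnel advances: compartment j to j+1, last to remission
  expect_equal(M["NMR3", "NMR4"], 1)
  expect_equal(M["NMR12", "Remission"], 1)
})

test_that("structural invariants hold across randomized cycles and inputs", {
  set.seed(21)
  for (rep in 1:20) {
    sh <- runif(3); sh <- sh / sum(sh)
    M <- build_transition_matrix(
      k = sample(0:575, 1), p_exit = runif(1, 0, 0.3),
      q_bg = runif(1, 0, 0.05),
      shares = c(locoregional = sh[1], metastatic = sh[2], death = sh[3]),
      p_rem_1l = runif(1, 0, 0.1), p_1l_2l = runif(1, 0, 0.2),
      p_2l_death = runif(1, 0, 0.2))
    expect_true(all(abs(rowSums(M) - 1) < 1e-12))
    expect_true(all(M >= 0 & M <= 1))
    expect_true(all(M[paste0("NMR", 1:12), "FirstLineMet"] == 0))
  }
})

test_that("all-zero hazards give identity rows for non-tunnel transient states", {
  M <- build_transition_matrix(k = 0, p_exit = 0, q_bg = 0,
                               shares = c(locoregional = 0.25,
                                          metastatic = 0.6, death = 0.15),
                               p_rem_1l = 0, p_1l_2l = 0, p_2l_death = 0,
                               treat_cycles = 10L)
  for (s in c("ResidualOn", "ResidualOff", "Remission", "FirstLineMet",
              "LaterLineMet")) {
    expect_equal(M[s, s], 1)
  }
})

test_that("matrix validation renormalizes tiny excess and rejects real excess", {
  M <- diag(2); dimnames(M) <- list(c("A", "B"), c("A", "B"))
  M[1, 2] <- 5e-10
  expect_equal(rowSums(validate_transition_matrix(M)), c(A = 1, B = 1))
  M[1, 2] <- 0.1
  expect_error(validate_transition_matrix(M), "'A'")
})

test_that("cohort propagation matches closed forms and conserves mass", {
  # identity matrices: constant trace
  I2 <- two_state_matrices(0, 5)
  tr <- run_cohort(c(1, 0), I2)
  expect_equal(unname(tr[, 1]), rep(1, 6))
  # constant hazard: alive occupancy is (1-p)^k
  p <- 0.1
  tr <- run_cohort(c(1, 0), two_state_matrices(p, 20))
  expect_equal(unname(tr[, 1]), (1 - p)^(0:20), tolerance = 1e-12)
  # death occupancy is monotone and bounded
  expect_true(all(diff(tr[, 2]) >= 0))
  expect_true(all(tr[, 2] >= 0 & tr[, 2] <= 1))
  expect_error(run_cohort(c(0.5, 0.4), two_state_matrices(p, 2)), "sum to 1")
  expect_error(run_cohort(c(1, 0, 0), two_state_matrices(p, 2)), "dimension")
})

test_that("half-cycle correction is the trapezoid of boundary occupancy", {
  # constant trace is unchanged
  tr <- matrix(rep(c(0.6, 0.4), each = 4), 4, 2)
  expect_equal(half_cycle_effective_occupancy(tr), tr[1:3, ])
  # a one-cycle collapse is averaged to one half
  tr <- rbind(c(1, 0), c(0, 1))
  expect_equal(half_cycle_effective_occupancy(tr),
               matrix(c(0.5, 0.5), 1, 2))
  # geometric decay matches an independent trapezoid computation
  p <- 0.2
  tr <- run_cohort(c(1, 0), two_state_matrices(p, 15))
  eff <- half_cycle_effective_occupancy(tr)
  oracle <- ((1 - p)^(0:14) + (1 - p)^(1:15)) / 2
  expect_equal(unname(eff[, 1]), oracle, tolerance = 1e-12)
  expect_equal(unname(rowSums(eff)), rep(1, 15), tolerance = 1e-12)
  # correction off: start-of-cycle occupancy
  expect_equal(half_cycle_effective_occupancy(tr, half_cycle = FALSE),
               tr[1:15, ])
})

test_that("discount factors follow (1+r)^(-k/12)", {
  expect_equal(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(12, 0.05), 1 / 1.05)
  expect_equal(discount_factor(0:100, 0), rep(1, 101))
  expect_equal(discount_factor(30, 0.05), 1.05^(-2.5))
  expect_error(discount_factor(3, -0.01), "non-negative")
})

test_that("micro-simulation oracle agrees with deterministic propagation", {
  # deterministic 0/1 matrices: exact agreement
  M <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE,
              dimnames = list(letters[1:3], letters[1:3]))
  ms <- microsim_cohort(c(1, 0, 0), rep(list(M), 4), n = 1000, seed = 3)
  expect_equal(ms, run_cohort(c(1, 0, 0), rep(list(M), 4)),
               ignore_attr = TRUE)
  # constant-hazard chain at n = 50000: within Monte-Carlo error
  ms <- microsim_cohort(c(1, 0), two_state_matrices(0.1, 10), 50000, seed = 9)
  truth <- 0.9^10
  se <- sqrt(truth * (1 - truth) / 50000)
  expect_lt(abs(ms[11, 1] - truth), 3 * se)
  # fixed seed: bit-identical rerun
  ms2 <- microsim_cohort(c(1, 0), two_state_matrices(0.1, 10), 50000, seed = 9)
  expect_identical(ms, ms2)
})
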
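# Markov engine: matrix validation (including the LTF death-rate rule),
# trace propagation against a matrix-power oracle, fundamental-matrix
# occupancy, and discounted payoff accumulation.

two_state_spec <- function(n_cycles = 10, discount = 0, cycle = 1,
                           half_cycle = FALSE) {
  model_spec(health_states(c("Alive", "Death")), cycle_length_years = cycle,
             n_cycles = n_cycles, discount_rate = discount,
             half_cycle = half_cycle, initial_distribution = c(1, 0))
}

named2 <- function(...) {
  m <- matrix(c(...), 2, 2, byrow = TRUE)
  dimnames(m) <- list(c("Alive", "Death"), c("Alive", "Death"))
  m
}

test_that("row-stochasticity and absorbing death are enforced", {
  spec <- model_spec(health_states(c("LXLD", "Death")),
                     initial_distribution = c(1, 0))
  ident <- diag(2); dimnames(ident) <- list(c("LXLD", "Death"), c("LXLD", "Death"))
  expect_silent(validate_matrix(ident, spec))
  bad <- ident; bad[1, 1] <- 0.98
  expect_error(validate_matrix(bad, spec), "LXLD",
               class = "radcea_validation_error")
  neg <- ident; neg[1, ] <- c(1.5, -0.5)
  expect_error(validate_matrix(neg, spec), class = "radcea_validation_error")
  notabs <- ident; notabs[2, ] <- c(0.5, 0.5)
  expect_error(validate_matrix(notabs, spec), "absorbing",
               class = "radcea_validation_error")
})

test_that("lost-to-follow-up patients must die at the cohort rate", {
  gt <- gen_transition_matrices(death_prob = 0.03, seed = 1)
  spec <- model_spec(gt$states, initial_distribution = c(1, 0, 0, 0, 0, 0))
  m <- gt$matrices[["3D-CRT"]]
  expect_silent(validate_matrix(m, spec))             # 0.03 vs 0.03
  expect_silent(validate_matrix(m, spec, death_prob = 0.03))
  bad <- m
  bad["LTF", "Death"] <- 0.05
  bad["LTF", "LTF"] <- 1 - 0.05
  expect_error(validate_matrix(bad, spec), "death rate",
               class = "radcea_validation_error")
  expect_error(validate_matrix(m, spec, death_prob = 0.05),
               class = "radcea_validation_error")
})

test_that("the trace is the repeated left-multiplication of the cohort row", {
  spec <- two_state_spec(3)
  # identity: fixed point
  trace <- run_cohort(two_state_spec(5), named2(1, 0, 0, 1))
  expect_true(all(trace$occupancy[, "Alive"] == 1))
  # geometric decay at 0.5 per cycle
  tr <- run_cohort(spec, named2(0.5, 0.5, 0, 1))
  expect_equal(unname(tr$occupancy[1:4, "Alive"]), c(1, 0.5, 0.25, 0.125))
  # random 4-state matrix vs independent matrix-power oracle
  set.seed(8)
  states <- c("A", "B", "C", "Death")
  m <- random_absorbing_matrix(states)
  spec4 <- model_spec(health_states(states), cycle_length_years = 1,
                      n_cycles = 10, discount_rate = 0,
                      initial_distribution = c(1, 0, 0, 0))
  tr4 <- run_cohort(spec4, m)
  expect_equal(unname(tr4$occupancy),
               unname(oracle_trace(c(1, 0, 0, 0), m, 10)), tolerance = 1e-12)
})

test_that("traces conserve mass and mortality is monotone", {
  set.seed(21)
  for (i in 1:25) {
    states <- c(paste0("S", 1:4), "Death")
    m <- random_absorbing_matrix(states)
    spec <- model_spec(health_states(states, death = "Death"),
                       n_cycles = 30, initial_distribution = c(1, 0, 0, 0, 0))
    tr <- run_cohort(spec, m)
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    dd <- diff(tr$occupancy[, "Death"])
    expect_true(all(dd >= -1e-12))
    expect_true(all(dd[1:5] > 0))  # strictly increasing while mass remains
  }
})

test_that("fundamental matrix gives expected cycles in transient states", {
  spec <- two_state_spec()
  expect_equal(expected_time_in_states(named2(0.5, 0.5, 0, 1), spec),
               c(Alive = 2))  # geometric 1 / (1 - 0.5), counting cycle 0
  # deterministic chain A -> B -> Death: one cycle in each
  states <- c("A", "B", "Death")
  chain <- matrix(c(0, 1, 0, 0, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE,
                  dimnames = list(states, states))
  spec3 <- model_spec(health_states(states), n_cycles = 5,
                      initial_distribution = c(1, 0, 0))
  expect_equal(expected_time_in_states(chain, spec3), c(A = 1, B = 1))
  # agrees with cumulative occupancy over a long horizon
  set.seed(4)
  states4 <- c("A", "B", "C", "Death")
  m <- random_absorbing_matrix(states4)
  spec4 <- model_spec(health_states(states4), n_cycles = 10000,
                      initial_distribution = c(1, 0, 0, 0))
  tr <- run_cohort(spec4, m)
  expect_equal(expected_time_in_states(m, spec4),
               colSums(tr$occupancy)[c("A", "B", "C")], tolerance = 1e-6)
  # a chain that never absorbs is rejected
  stuck <- diag(3); dimnames(stuck) <- list(states, states)
  expect_error(expected_time_in_states(stuck, spec3),
               class = "radcea_validation_error")
})

test_that("payoff accumulation matches closed forms", {
  # full health over the whole horizon, no discounting: QALY = horizon
  spec <- two_state_spec(10)
  pay <- state_payoffs(c(Alive = 1), c(Alive = 0), spec = spec)
  out <- expected_outcomes(run_cohort(spec, named2(1, 0, 0, 1)), pay)
  expect_equal(out$qaly, 10)
  # geometric survival: QALY = u * sum s^t
  s <- 0.8; u <- 0.7; n <- 12
  spec2 <- two_state_spec(n)
  pay2 <- state_payoffs(c(Alive = u), c(Alive = 100), spec = spec2)
  out2 <- expected_outcomes(run_cohort(spec2, named2(s, 1 - s, 0, 1)), pay2)
  expect_equal(out2$qaly, u * sum(s^(1:n)), tolerance = 1e-12)
  expect_equal(out2$cost, 100 * sum(s^(1:n)), tolerance = 1e-12)
  # calibrated single-state fixture reproduces the study base case
  spec3 <- two_state_spec(5)
  pay3 <- state_payoffs(c(Alive = 0.726), c(Alive = 1841.952), spec = spec3)
  out3 <- expected_outcomes(run_cohort(spec3, named2(1, 0, 0, 1)), pay3)
  expect_equal(out3$cost, 9209.76, tolerance = 1e-9)
  expect_equal(out3$qaly, 3.63, tolerance = 1e-9)
})

test_that("discounting never increases totals and vanishes at rate zero", {
  m <- named2(0.9, 0.1, 0, 1)
  pay_at <- function(spec) state_payoffs(c(Alive = 0.8), c(Alive = 50), spec = spec)
  undisc <- expected_outcomes(run_cohort(two_state_spec(20), m),
                              pay_at(two_state_spec(20)))
  disc_spec <- two_state_spec(20, discount = 0.03)
  disc <- expected_outcomes(run_cohort(disc_spec, m), pay_at(disc_spec))
  expect_lt(disc$cost, undisc$cost)
  expect_lt(disc$qaly, undisc$qaly)
  zero_spec <- two_state_spec(20, discount = 0)
  expect_equal(expected_outcomes(run_cohort(zero_spec, m), pay_at(zero_spec)),
               undisc)
})

test_that("half-cycle correction lies between the two uncorrected conventions", {
  m <- named2(0.85, 0.15, 0, 1)
  for (disc in c(0, 0.03)) {
    spec <- two_state_spec(15, discount = disc)
    pay <- state_payoffs(c(Alive = 0.75), c(Alive = 120), spec = spec)
    tr <- run_cohort(spec, m)
    e <- expected_outcomes(tr, pay, convention = "end")
    s <- expected_outcomes(tr, pay, convention = "start")
    h <- expected_outcomes(tr, pay, convention = "half")
    expect_gt(h$qaly, min(e$qaly, s$qaly)); expect_lt(h$qaly, max(e$qaly, s$qaly))
    expect_gt(h$cost, min(e$cost, s$cost)); expect_lt(h$cost, max(e$cost, s$cost))
  }
  # the spec flag routes to the half convention
  spec_h <- two_state_spec(15, half_cycle = TRUE)
  pay_h <- state_payoffs(c(Alive = 0.75), c(Alive = 120), spec = spec_h)
  tr_h <- run_cohort(spec_h, m)
  expect_equal(expected_outcomes(tr_h, pay_h),
               expected_outcomes(tr_h, pay_h, convention = "half"))
})

test_that("upfront costs accrue once at cycle 0, undiscounted", {
  spec <- two_state_spec(5, discount = 0.05)
  m <- named2(1, 0, 0, 1)
  base <- state_payoffs(c(Alive = 1), c(Alive = 10), spec = spec)
  up <- state_payoffs(c(Alive = 1), c(Alive = 10), upfront = 500, spec = spec)
  tr <- run_cohort(spec, m)
  expect_equal(expected_outcomes(tr, up)$cost,
               expected_outcomes(tr, base)$cost + 500)
})

test_that("payoffs must cover the trace's states with zero at death", {
  spec <- two_state_spec(5)
  expect_error(state_payoffs(c(Alive = 1, Death = 0.1), c(Alive = 0),
                             spec = spec), class = "radcea_invalid_input")
  other <- model_spec(health_states(c("X", "Death")),
                      initial_distribution = c(1, 0))
  pay_other <- state_payoffs(c(X = 1), c(X = 0), spec = other)
  tr <- run_cohort(spec, named2(1, 0, 0, 1))
  expect_error(expected_outcomes(tr, pay_other), class = "radcea_invalid_input")
})
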
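# One-way / tornado analysis, moment matching, the Monte Carlo PSA, and
# acceptability curves.

# two strategies, one alive state, 5 undiscounted one-year cycles, no
# deaths: outcomes are linear in every payoff parameter
linear_model <- function(u_ref = 0.7, u_cmp = 0.6, c_ref = 100, c_cmp = 150) {
  states <- health_states(c("Alive", "Death"))
  spec <- model_spec(states, cycle_length_years = 1, n_cycles = 5,
                     discount_rate = 0, initial_distribution = c(1, 0))
  m <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(states$name, states$name))
  mk <- function(u, cc) list(transition = m,
                             payoffs = state_payoffs(c(Alive = u),
                                                     c(Alive = cc), spec = spec))
  cea_model(spec, list(ref = mk(u_ref, c_ref), cmp = mk(u_cmp, c_cmp)),
            reference = "ref")
}

test_that("one-way swing is zero for a degenerate range and exact on a linear model", {
  model <- linear_model()
  p0 <- param_spec("u", "utility:ref:Alive", low = 0.7, high = 0.7)
  expect_equal(one_way(model, p0, outcome = "delta_qaly")$swing, 0)
  p <- param_spec("u", "utility:ref:Alive", low = 0.6, high = 0.8)
  bar <- one_way(model, p, outcome = "delta_qaly")
  expect_equal(bar$swing, 5 * 0.2)  # 5 years x utility range, exactly
  # evaluating restores nothing: the model itself is unchanged
  expect_equal(evaluate_strategies(model)$qaly, c(3.5, 3.0))
})

test_that("a wider range on the same linear target gives the larger swing", {
  model <- linear_model()
  narrow <- one_way(model, param_spec("n", "utility:ref:Alive", 0.65, 0.75),
                    outcome = "delta_qaly")
  wide <- one_way(model, param_spec("w", "utility:ref:Alive", 0.60, 0.80),
                  outcome = "delta_qaly")
  expect_gt(wide$swing, narrow$swing)
})

test_that("one-way rejects whole-row targets and unresolvable paths", {
  model <- linear_model()
  expect_error(one_way(model, param_spec("r", "row:ref:Alive",
                                         distribution = "dirichlet_row",
                                         concentration = c(50, 1))),
               class = "radcea_config_error")
  expect_error(one_way(model, param_spec("x", "utility:ref:Nowhere", 0, 1)),
               class = "radcea_config_error")
})

test_that("tornado sorts by descending swing, stably for ties", {
  bars <- tibble::tibble(param = c("a", "b", "c"),
                         outcome_low = 0, outcome_high = c(1, 3, 2),
                         swing = c(1, 3, 2))
  expect_equal(tornado(bars)$param, c("b", "c", "a"))
  ties <- tibble::tibble(param = c("x", "y", "z"), outcome_low = 0,
                         outcome_high = 1, swing = 1)
  expect_equal(tornado(ties)$param, c("x", "y", "z"))
  expect_error(tornado(ties[0, ]), class = "radcea_invalid_input")
})

test_that("the toxicity fixture's tornado is led by the reference LXLD and HXLD utilities", {
  tox <- gen_toxicity_fixture()
  torn <- tornado_analysis(tox$model, tox$params, outcome = "nmb", wtp = 10000)
  expect_setequal(torn$param[1:2],
                  c("utility LXLD 3D-CRT", "utility HXLD 3D-CRT"))
})

test_that("method-of-moments hyperparameters reproduce the requested moments", {
  hp <- moment_match_beta(0.2, 0.05)
  expect_equal(hp$alpha, 12.6)
  expect_equal(hp$beta, 50.4)
  set.seed(1)
  draws <- stats::rbeta(1e5, hp$alpha, hp$beta)
  expect_lt(abs(mean(draws) - 0.2), 0.005)
  hg <- moment_match_gamma(40, 8)
  set.seed(2)
  g <- stats::rgamma(1e5, shape = hg$shape, rate = hg$rate)
  expect_lt(abs(mean(g) - 40), 3 * 8 / sqrt(1e5))
  expect_lt(abs(sd(g) - 8), 3 * 8 / sqrt(1e5))
  expect_error(moment_match_beta(0.5, 0.6), class = "radcea_config_error")
  expect_error(moment_match_gamma(-1, 1), class = "radcea_config_error")
})

test_that("parameter draws are reproducible and fixed parameters stay at base", {
  fx <- gen_calibrated_fixture()
  fixed <- dplyr::mutate(fx$params, distribution = "fixed")
  set.seed(10)
  expect_identical(evaluate_strategies(draw_parameters(fx$model, fixed)),
                   evaluate_strategies(fx$model))
  set.seed(11); m1 <- draw_parameters(fx$model, fx$params)
  set.seed(11); m2 <- draw_parameters(fx$model, fx$params)
  expect_identical(evaluate_strategies(m1), evaluate_strategies(m2))
})

test_that("dirichlet rows sum to one and respect concentrations", {
  model <- linear_model()
  p <- param_spec("row", "row:ref:Alive", distribution = "dirichlet_row",
                  concentration = c(95, 5))
  set.seed(3)
  for (i in 1:20) {
    drawn <- draw_parameters(model, p)
    row <- drawn$strategies$ref$transition["Alive", ]
    expect_equal(sum(row), 1, tolerance = 1e-12)
    expect_true(all(row >= 0))
  }
})

test_that("scalar transition perturbation renormalises around a fixed death column", {
  gt <- gen_transition_matrices(death_prob = 0.02, ltf_prob = 0.03, seed = 6)
  spec <- model_spec(gt$states, initial_distribution = c(1, 0, 0, 0, 0, 0))
  util <- c(LXLD = 0.8, LXHD = 0.7, HXLD = 0.7, HXHD = 0.5, LTF = 0.7)
  cost <- setNames(rep(10, 5), names(util))
  model <- cea_model(spec, list(
    a = list(transition = gt$matrices[[1]],
             payoffs = state_payoffs(util, cost, spec = spec)),
    b = list(transition = gt$matrices[[2]],
             payoffs = state_payoffs(util, cost, spec = spec))),
    reference = "a", death_prob = 0.02)
  bar <- one_way(model, param_spec("t", "transition:a:LXLD:LXHD",
                                   low = 0.0,
                                   high = 0.3),
                 outcome = "delta_qaly")
  expect_true(is.finite(bar$swing))
  # perturbed matrices keep the death column and stay valid
  pert <- radcea:::set_target(model, "transition:a:LXLD:LXHD", 0.3)
  m2 <- pert$strategies$a$transition
  expect_equal(unname(m2["LXLD", "Death"]), 0.02)
  expect_silent(validate_matrix(m2, spec, death_prob = 0.02))
  # death-column targets are refused
  expect_error(radcea:::set_target(model, "transition:a:LXLD:Death", 0.5),
               class = "radcea_config_error")
})

test_that("zero-variance PSA reproduces the base case bitwise", {
  fx <- gen_calibrated_fixture()
  fixed <- dplyr::mutate(fx$params, distribution = "fixed")
  psa <- run_psa(fx$model, fixed, n_draws = 25, seed = 42)
  base <- evaluate_strategies(fx$model)
  for (d in 1:25) {
    got <- psa$samples[psa$samples$draw == d, c("strategy", "cost", "qaly")]
    expect_identical(got$cost, base$cost)
    expect_identical(got$qaly, base$qaly)
  }
  expect_true(all(psa$deltas$delta_cost == psa$deltas$delta_cost[1]))
})

test_that("extending the number of draws preserves the earlier stream", {
  fx <- gen_calibrated_fixture()
  short <- run_psa(fx$model, fx$params, n_draws = 20, seed = 9)
  long <- run_psa(fx$model, fx$params, n_draws = 40, seed = 9)
  expect_identical(short$samples,
                   long$samples[long$samples$draw <= 20, ])
})

test_that("draws that can never validate hit the attempt cap", {
  # perturbing the death row destroys absorption in every draw
  model <- linear_model()
  p <- param_spec("bad", "row:ref:Death", distribution = "dirichlet_row",
                  concentration = c(10, 10))
  expect_error(run_psa(model, p, n_draws = 1, seed = 1),
               class = "radcea_validation_error")
})

test_that("quadrants follow the clockwise convention with flagged axes", {
  q <- radcea:::classify_quadrant(c(1, 1, -1, -1, 0, 0, 2, -2),
                                  c(1, -1, -1, 1, 1, -1, 0, 0))
  expect_equal(q$quadrant, c("I", "II", "III", "IV", "I", "II", "I", "III"))
  expect_equal(q$on_axis, c(rep(FALSE, 4), rep(TRUE, 4)))
  # shares over samples sum to 1
  fx <- gen_calibrated_fixture()
  psa <- run_psa(fx$model, fx$params, n_draws = 50, seed = 2)
  expect_equal(sum(quadrant_shares(psa)$share), 1)
})

test_that("CEAC probabilities are coherent and reduce to cost at WTP zero", {
  fx <- gen_calibrated_fixture()
  psa <- run_psa(fx$model, fx$params, n_draws = 200, seed = 12)
  cc <- tibble::as_tibble(ceac(psa, wtp_grid = c(0, 5000, 20000)))
  sums <- tapply(cc$probability, cc$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  # at WTP 0 the winner is simply the cheaper strategy in each draw
  wide <- tidyr::pivot_wider(psa$samples, id_cols = "draw",
                             names_from = "strategy", values_from = "cost")
  frac_ref_cheaper <- mean(wide$`3D-CRT` < wide$IMRT)
  expect_equal(cc$probability[cc$wtp == 0 & cc$strategy == "3D-CRT"],
               frac_ref_cheaper)
  expect_error(ceac(psa, wtp_grid = c(-1, 10)), class = "radcea_invalid_input")
})

test_that("a strategy dominant in every draw has a flat CEAC at one", {
  fx <- gen_calibrated_fixture()
  fixed <- dplyr::mutate(fx$params, distribution = "fixed")
  psa <- run_psa(fx$model, fixed, n_draws = 10, seed = 3)
  cc <- tibble::as_tibble(ceac(psa))
  expect_true(all(cc$probability[cc$strategy == "3D-CRT"] == 1))
})
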
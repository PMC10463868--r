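# The strategy-comparison bundle: one model spec shared by all
# strategies, each strategy carrying its own transition matrix and
# payoffs. Strategies are fully independent model instances; nothing is
# shared unless the configuration says so.

#' Bundle strategies into a comparable decision model
#'
#' @param spec A `model_spec` shared by all strategies.
#' @param strategies Named list; each element a list with `transition`
#'   (matrix) and `payoffs` (a `state_payoffs`).
#' @param reference Name of the reference strategy for incremental
#'   quantities (default: the first strategy).
#' @param death_prob Optional per-cycle cohort death probability used by
#'   matrix validation.
#' @return A `cea_model` object.
#' @export
cea_model <- function(spec, strategies, reference = names(strategies)[1],
                      death_prob = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  if (is.null(names(strategies)) || any(names(strategies) == "") ||
      anyDuplicated(names(strategies))) {
    abort_invalid("`strategies` must be a uniquely named list")
  }
  if (!reference %in% names(strategies)) {
    abort_invalid("`reference` must name one of the strategies")
  }
  for (nm in names(strategies)) {
    st <- strategies[[nm]]
    if (!all(c("transition", "payoffs") %in% names(st))) {
      abort_invalid(sprintf("strategy `%s` needs `transition` and `payoffs`", nm))
    }
    strategies[[nm]]$transition <-
      transition_matrix(validate_matrix(st$transition, spec,
                                        death_prob = death_prob),
                        strategy = nm)
    if (!inherits(st$payoffs, "state_payoffs")) {
      abort_invalid(sprintf("strategy `%s` payoffs must be state_payoffs()", nm))
    }
  }
  structure(list(spec = spec, strategies = strategies,
                 reference = reference, death_prob = death_prob),
            class = "cea_model")
}

#' @export
print.cea_model <- function(x, ...) {
  cat("Decision model:", length(x$strategies), "strategies (",
      paste(names(x$strategies), collapse = ", "), "), reference",
      x$reference, "\n")
  print(x$spec)
  invisible(x)
}

#' Evaluate every strategy's discounted cost and QALYs
#'
#' Runs the cohort trace and payoff accumulation for each strategy in
#' the model.
#'
#' @param model A `cea_model`.
#' @return Tibble with one row per strategy: `strategy`, `cost`, `qaly`.
#' @export
evaluate_strategies <- function(model) {
  stopifnot(inherits(model, "cea_model"))
  purrr::map_dfr(names(model$strategies), function(nm) {
    st <- model$strategies[[nm]]
    trace <- run_cohort(model$spec, st$transition,
                        death_prob = model$death_prob)
    expected_outcomes(trace, st$payoffs)
  })
}

#' Read a decision model from a YAML specification
#'
#' The YAML carries `states` (with `death` and optional `ltf` markers),
#' run controls (`cycle_length_years`, `n_cycles`, `discount_rate`,
#' `half_cycle`, `initial_distribution`, `death_prob`), and per-strategy
#' blocks each with a row-major `transition_matrix`, `state_utilities`,
#' `state_costs`, and optional `upfront_cost`. `reference` names the
#' reference strategy.
#'
#' @param path Path to a YAML file.
#' @param state_utilities Optional tibble from [state_utilities()] used
#'   to fill any strategy whose `state_utilities` key is absent (matched
#'   by `arm` = strategy name and `state_label` = state name).
#' @return A `cea_model`.
#' @export
read_model_spec <- function(path, state_utilities = NULL) {
  cfg <- yaml::read_yaml(path)
  req <- c("states", "strategies")
  if (!all(req %in% names(cfg))) {
    abort_config("model YAML needs `states` and `strategies` keys")
  }
  states <- health_states(vapply(cfg$states, function(s) s$name, character(1)),
                          death = cfg$death %||% "Death",
                          ltf = cfg$ltf)
  spec <- model_spec(
    states,
    cycle_length_years = cfg$cycle_length_years %||% 0.25,
    n_cycles = cfg$n_cycles %||% 20L,
    discount_rate = cfg$discount_rate %||% 0.03,
    half_cycle = cfg$half_cycle %||% FALSE,
    initial_distribution = unlist(cfg$initial_distribution) %||% NULL
  )
  n <- nrow(states)
  strategies <- purrr::imap(cfg$strategies, function(st, nm) {
    tm <- matrix(unlist(st$transition_matrix), nrow = n, byrow = TRUE,
                 dimnames = list(states$name, states$name))
    util <- unlist(st$state_utilities)
    if (is.null(util) && !is.null(state_utilities)) {
      rows <- state_utilities[state_utilities$arm == nm, , drop = FALSE]
      util <- setNames(rows$mean, rows$state_label)
    }
    if (is.null(util)) {
      abort_config(sprintf("strategy `%s` has no state utilities", nm))
    }
    cost <- unlist(st$state_costs)
    if (is.null(cost)) {
      abort_config(sprintf("strategy `%s` has no state costs", nm))
    }
    list(transition = tm,
         payoffs = state_payoffs(util, cost,
                                 upfront = st$upfront_cost %||% 0,
                                 spec = spec))
  })
  cea_model(spec, strategies,
            reference = cfg$reference %||% names(strategies)[1],
            death_prob = cfg$death_prob)
}
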
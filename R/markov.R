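# Cohort Markov engine: six-state toxicity model (composite
# xerostomia x dysphagia states + lost-to-follow-up + death), cohort
# trace, fundamental-matrix occupancy, and discounted cost/QALY
# accumulation.

#' Define the model's health states
#'
#' A state table for the cohort model. Exactly one state is the absorbing
#' death state; at most one state is flagged lost-to-follow-up (LTF) —
#' patients there are unobserved but are assumed to die at the same
#' per-cycle rate as the rest of the cohort, which [validate_matrix()]
#' enforces.
#'
#' @param names Character vector of state names (must include `death`).
#' @param death Name of the absorbing death state (default `"Death"`).
#' @param ltf Name of the lost-to-follow-up state, or `NULL` if none.
#' @return Tibble with columns `name`, `absorbing`, `lost_to_follow_up`.
#' @export
health_states <- function(names, death = "Death", ltf = NULL) {
  if (anyDuplicated(names)) abort_invalid("state names must be unique")
  if (!death %in% names) abort_invalid("`death` must be one of the state names")
  if (!is.null(ltf)) {
    if (!ltf %in% names) abort_invalid("`ltf` must be one of the state names")
    if (ltf == death) abort_invalid("the LTF state cannot be the death state")
  }
  tibble(name = names,
         absorbing = names == death,
         lost_to_follow_up = if (is.null(ltf)) FALSE else names == ltf)
}

#' Default six-state toxicity state set
#'
#' Composite xerostomia-by-dysphagia states (low/high each), plus
#' lost-to-follow-up and death: LXLD, LXHD, HXLD, HXHD, LTF, Death.
#' State names are labels only; any state set built with
#' [health_states()] runs.
#'
#' @return A state tibble.
#' @export
toxicity_states <- function() {
  health_states(c("LXLD", "LXHD", "HXLD", "HXHD", "LTF", "Death"),
                death = "Death", ltf = "LTF")
}

#' Build a Markov model specification
#'
#' Run controls for the cohort simulation. Defaults: quarterly cycles
#' over a 5-year horizon, 3%/year discounting of both costs and QALYs,
#' no half-cycle correction, cohort starting in the first state.
#'
#' @param states A state tibble from [health_states()].
#' @param cycle_length_years Positive cycle length in years.
#' @param n_cycles Positive integer number of cycles (horizon =
#'   `n_cycles * cycle_length_years`).
#' @param discount_rate Annual discount rate (>= 0), applied to costs and
#'   QALYs alike.
#' @param half_cycle Logical; apply the half-cycle correction (average of
#'   adjacent trace rows) when accumulating payoffs.
#' @param initial_distribution Non-negative vector over states summing
#'   to 1; default all cohort mass in the first state.
#' @return A `model_spec` object.
#' @export
model_spec <- function(states, cycle_length_years = 0.25, n_cycles = 20,
                       discount_rate = 0.03, half_cycle = FALSE,
                       initial_distribution = NULL) {
  if (!is.data.frame(states) ||
      !all(c("name", "absorbing", "lost_to_follow_up") %in% names(states))) {
    abort_invalid("`states` must come from health_states()")
  }
  if (sum(states$absorbing) != 1) abort_invalid("exactly one absorbing death state")
  if (sum(states$lost_to_follow_up) > 1) abort_invalid("at most one LTF state")
  if (cycle_length_years <= 0) abort_invalid("`cycle_length_years` must be positive")
  if (n_cycles < 1 || n_cycles != round(n_cycles)) {
    abort_invalid("`n_cycles` must be a positive integer")
  }
  if (discount_rate < 0) abort_invalid("`discount_rate` must be >= 0")
  n <- nrow(states)
  if (is.null(initial_distribution)) {
    initial_distribution <- c(1, rep(0, n - 1))
  }
  if (length(initial_distribution) != n || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-9) {
    abort_invalid("`initial_distribution` must be non-negative over states and sum to 1")
  }
  structure(
    list(states = as_tibble(states),
         cycle_length_years = cycle_length_years,
         n_cycles = as.integer(n_cycles),
         discount_rate = discount_rate,
         half_cycle = isTRUE(half_cycle),
         initial_distribution = setNames(initial_distribution, states$name)),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Markov model spec:", nrow(x$states), "states,",
      x$n_cycles, "cycles of", x$cycle_length_years, "years,",
      "discount", x$discount_rate, "/yr,",
      if (x$half_cycle) "half-cycle corrected\n" else "cycle-end convention\n")
  invisible(x)
}

#' Attach a strategy label to a transition matrix
#'
#' @param m Square numeric matrix with rows/columns named by state.
#' @param strategy Strategy label.
#' @return The matrix with a `strategy` attribute.
#' @export
transition_matrix <- function(m, strategy = "strategy") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort_invalid("transition matrix must be square")
  attr(m, "strategy") <- strategy
  m
}

#' Validate a transition matrix against a model specification
#'
#' Checks (each within 1e-9): dimensions match the state set, all entries
#' non-negative, every row sums to 1, the death row is the identity on
#' death, and — when an LTF state exists — that the LTF state's
#' transition probability to death equals the cohort's per-cycle death
#' probability (patients lost to follow-up are assumed to die at the same
#' rate as the observed cohort). If `death_prob` is not supplied it is
#' inferred from the death-column entries of the non-LTF alive states,
#' which must then agree with one another.
#'
#' @param m Transition matrix (state-by-state, row-stochastic).
#' @param spec A `model_spec`.
#' @param death_prob Optional configured per-cycle cohort death
#'   probability.
#' @param tol Numerical tolerance (default 1e-9).
#' @return The matrix, invisibly, with rows/columns named by state.
#' @export
validate_matrix <- function(m, spec, death_prob = NULL, tol = 1e-9) {
  stopifnot(inherits(spec, "model_spec"))
  states <- spec$states$name
  n <- length(states)
  m <- as.matrix(m)
  if (!all(dim(m) == n)) {
    abort_validation(sprintf("matrix is %dx%d but the model has %d states",
                             nrow(m), ncol(m), n))
  }
  if (is.null(rownames(m))) dimnames(m) <- list(states, states)
  if (!identical(rownames(m), states) || !identical(colnames(m), states)) {
    abort_validation("matrix dimnames must match the state names in order")
  }
  if (any(m < -tol)) {
    bad <- which(m < -tol, arr.ind = TRUE)[1, ]
    abort_validation(sprintf("negative transition probability at %s -> %s",
                             states[bad[1]], states[bad[2]]))
  }
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    bad <- states[which.max(abs(rs - 1))]
    abort_validation(sprintf("row `%s` sums to %.12g, not 1", bad,
                             rs[which.max(abs(rs - 1))]))
  }
  death <- states[spec$states$absorbing]
  if (abs(m[death, death] - 1) > tol) {
    abort_validation("the death state must be absorbing (death row = identity on death)")
  }
  if (any(spec$states$lost_to_follow_up)) {
    ltf <- states[spec$states$lost_to_follow_up]
    if (is.null(death_prob)) {
      alive <- setdiff(states, c(death, ltf))
      dp <- m[alive, death]
      if (length(dp) && diff(range(dp)) > tol) {
        abort_validation(paste0(
          "cannot infer the cohort death rate: non-LTF alive states have ",
          "unequal death probabilities; pass `death_prob` explicitly"))
      }
      death_prob <- if (length(dp)) dp[[1]] else m[ltf, death]
    }
    if (abs(m[ltf, death] - death_prob) > tol) {
      abort_validation(sprintf(
        "LTF -> death probability %.12g differs from the cohort death rate %.12g",
        m[ltf, death], death_prob))
    }
  }
  invisible(m)
}

#' Run the cohort simulation
#'
#' Propagates the cohort distribution through `n_cycles` matrix
#' multiplications: occupancy at cycle t+1 is occupancy at cycle t times
#' the transition matrix. Row 0 of the trace is the initial distribution.
#'
#' @param spec A `model_spec`.
#' @param m A validated transition matrix.
#' @param death_prob Optional cohort death probability for validation.
#' @return A `cohort_trace` object wrapping the
#'   `(n_cycles + 1) x n_states` occupancy matrix.
#' @export
run_cohort <- function(spec, m, death_prob = NULL) {
  m <- validate_matrix(m, spec, death_prob = death_prob)
  n <- nrow(spec$states)
  occ <- matrix(0, nrow = spec$n_cycles + 1, ncol = n,
                dimnames = list(0:spec$n_cycles, spec$states$name))
  occ[1, ] <- spec$initial_distribution
  for (t in seq_len(spec$n_cycles)) {
    occ[t + 1, ] <- occ[t, ] %*% m
  }
  structure(list(occupancy = occ, spec = spec,
                 strategy = attr(m, "strategy") %||% "strategy"),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace (", x$strategy, "): ",
      nrow(x$occupancy) - 1, " cycles x ", ncol(x$occupancy), " states\n",
      sep = "")
  print(utils::head(round(x$occupancy, 4)))
  if (nrow(x$occupancy) > 6) cat("...\n")
  invisible(x)
}

#' @describeIn run_cohort Long tibble of the trace: `cycle`, `state`,
#'   `occupancy`, `years` (cycle end in years).
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @method tidy cohort_trace
#' @export
tidy.cohort_trace <- function(x, ...) {
  occ <- x$occupancy
  tibble(cycle = rep(as.integer(rownames(occ)), times = ncol(occ)),
         state = rep(colnames(occ), each = nrow(occ)),
         occupancy = as.vector(occ)) %>%
    mutate(years = .data$cycle * x$spec$cycle_length_years,
           strategy = x$strategy) %>%
    select("strategy", "cycle", "years", "state", "occupancy")
}

#' @describeIn run_cohort State-occupancy curves over the model horizon.
#' @param object A `cohort_trace`.
#' @method autoplot cohort_trace
#' @export
autoplot.cohort_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$years, y = .data$occupancy,
                                   colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Years", y = "Cohort fraction",
                  title = paste("Cohort trace:", object$strategy)) +
    ggplot2::theme_minimal()
}

#' Expected cycles spent in each transient state
#'
#' Closed-form occupancy from the fundamental matrix of the absorbing
#' chain: with Q the transient-to-transient block, the expected number of
#' cycles in each transient state (starting from the initial
#' distribution over transient states) is given by rows of
#' solve(I - Q). Serves as an exact oracle for undiscounted trace
#' accumulation.
#'
#' @param m Transition matrix.
#' @param spec A `model_spec` (identifies absorbing states and the
#'   initial distribution).
#' @return Named numeric vector of expected cycle counts per transient
#'   state, from the spec's initial distribution.
#' @export
expected_time_in_states <- function(m, spec) {
  m <- validate_matrix(m, spec)
  transient <- spec$states$name[!spec$states$absorbing]
  q <- m[transient, transient, drop = FALSE]
  fundamental <- tryCatch(
    solve(diag(length(transient)) - q),
    error = function(e) abort_validation(
      "no absorption: (I - Q) is singular, the chain never reaches death")
  )
  init <- spec$initial_distribution[transient]
  # counts cycles 0, 1, 2, ... including occupancy at cycle 0
  drop(init %*% fundamental)
}

#' Define state payoffs
#'
#' Per-state utility (per year, so QALY accrual scales with cycle length)
#' and cost per cycle, plus an optional one-off upfront cost added
#' undiscounted at cycle 0 (e.g. the radiotherapy course itself when not
#' folded into per-cycle state costs). Death carries zero payoff by
#' definition.
#'
#' @param utility Named numeric vector, one utility per state.
#' @param cost Named numeric vector, one per-cycle cost (>= 0) per state.
#' @param upfront One-off cost at cycle 0 (default 0).
#' @param spec A `model_spec` used to check names and the death-zero rule.
#' @return A `state_payoffs` object.
#' @export
state_payoffs <- function(utility, cost, upfront = 0, spec) {
  stopifnot(inherits(spec, "model_spec"))
  states <- spec$states$name
  death <- states[spec$states$absorbing]
  for (nm in setdiff(states, c(death, names(utility)))) utility[nm] <- 0
  for (nm in setdiff(states, c(death, names(cost)))) cost[nm] <- 0
  if (!death %in% names(utility)) utility[death] <- 0
  if (!death %in% names(cost)) cost[death] <- 0
  utility <- utility[states]
  cost <- cost[states]
  if (anyNA(utility) || anyNA(cost)) abort_invalid("payoffs contain NA")
  if (utility[death] != 0 || cost[death] != 0) {
    abort_invalid("death payoffs must be exactly 0")
  }
  if (any(cost < 0)) abort_invalid("state costs must be >= 0")
  if (upfront < 0) abort_invalid("`upfront` must be >= 0")
  structure(list(utility = utility, cost = cost, upfront = upfront),
            class = "state_payoffs")
}

#' Discounted cost and QALY totals from a cohort trace
#'
#' Accumulates payoffs from cycle 1 onward (cycle-end convention; cycle-0
#' occupancy earns nothing except the upfront cost). For cycle t the
#' cycle reward is the occupancy-weighted payoff, QALYs scaled by the
#' cycle length in years, and both streams discounted by
#' `(1 + discount_rate)^(-t * cycle_length_years)`. With the half-cycle
#' correction, the occupancy used for cycle t is the average of rows
#' t - 1 and t, which places transitions mid-cycle and lies between the
#' start-of-cycle and end-of-cycle conventions.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param payoffs A `state_payoffs` object.
#' @param convention Override of the accumulation convention, one of
#'   `"spec"` (use the spec's half-cycle flag), `"end"`, `"start"`,
#'   `"half"`. Mainly for convention-comparison studies.
#' @return One-row tibble with `strategy`, `cost`, `qaly`.
#' @export
expected_outcomes <- function(trace, payoffs, convention = "spec") {
  stopifnot(inherits(trace, "cohort_trace"), inherits(payoffs, "state_payoffs"))
  spec <- trace$spec
  occ <- trace$occupancy
  if (!identical(colnames(occ), names(payoffs$utility))) {
    abort_invalid("payoff states do not match the trace states")
  }
  convention <- match.arg(convention, c("spec", "end", "start", "half"))
  if (convention == "spec") convention <- if (spec$half_cycle) "half" else "end"

  tt <- seq_len(spec$n_cycles)
  occ_used <- switch(convention,
    end   = occ[tt + 1, , drop = FALSE],
    start = occ[tt, , drop = FALSE],
    half  = (occ[tt, , drop = FALSE] + occ[tt + 1, , drop = FALSE]) / 2
  )
  disc <- (1 + spec$discount_rate)^(-tt * spec$cycle_length_years)
  cost <- payoffs$upfront +
    sum(disc * (occ_used %*% payoffs$cost))
  qaly <- sum(disc * (occ_used %*% payoffs$utility) * spec$cycle_length_years)
  tibble(strategy = trace$strategy, cost = cost, qaly = qaly)
}
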